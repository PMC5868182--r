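format-version: 1.2

[Term]
id: HP:0000118
name: Phenotypic abnormality

[Term]
id: HP:0000707
name: Abnormality of the nervous system
is_a: HP:0000118

[Term]
id: HP:0002185
name: Neurofibrillary tangles
is_a: HP:0000707

[Term]
id: HP:0012103
name: Amyloid angiopathy
is_a: HP:0000707

[Term]
id: HP:0011970
name: Cerebral amyloid angiopathy
is_a: HP:0012103

[Term]
id: HP:0001250
name: Seizure
synonym: "Seizures" EXACT []
synonym: "Epileptic seizure" EXACT []
is_a: HP:0000707

[Term]
id: HP:0000365
name: Hearing loss
synonym: "Deafness" EXACT []
is_a: HP:0000118

[Term]
id: HP:0999999
name: Obsolete thing
is_a: HP:0000118
is_obsolete: true
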