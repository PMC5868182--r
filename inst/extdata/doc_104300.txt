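A progressive neurodegenerative disorder with onset in late adulthood.

## Clinical Features
Yan et al. (1996) reported deposits close to neurofibrillary  tangles
in affected neurons.

Bergeron et al. (1987) found that cerebral amyloid angiopathy is an
integral component of the disease, often accompanied by seizures.

## Molecular Genetics
Mutations in this model system cause hearing loss in carriers.

## Diagnosis
Patients showed hearing loss and isolated epileptic seizure episodes.
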