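104300	HP:0002185	NEUROFIBRILLARYTANGLES	2
104300	HP:0011970	CEREBRALAMYLOIDANGIOPATHY	3
104300	HP:0001250	SEIZURES	3
104300	HP:0000365	HEARINGLOSS	4
104300	HP:0001250	EPILEPTICSEIZURE	4
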