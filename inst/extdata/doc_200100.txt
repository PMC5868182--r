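An early report described recurrent seizures in two siblings.

## clinical features
A later study confirmed seizures and progressive deafness.

## other features
No additional findings were reported.
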