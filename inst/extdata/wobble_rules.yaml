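# Unique wobble-paired anticodon used for codons whose Watson-Crick
# anticodon is absent from the tRNA pool. Keyed by the codon's third base;
# the value is the wobble (position 34) base of the pairing anticodon.
# T -> G models G:T wobble, G -> T models T:G wobble, C -> A and A -> A
# model decoding by inosine (written as its genomically encoded A).
T: G
G: T
C: A
A: A
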