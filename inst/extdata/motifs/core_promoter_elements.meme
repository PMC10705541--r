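# Consensus-derived reconstructions (IUPAC consensus -> probabilities); synthetic, not experimentally fitted matrices.
MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF INR
letter-probability matrix: alphabet= 4 w= 6 nsites= 20 E= 0
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.960000 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.020000 0.480000 0.020000 0.480000

MOTIF TATA
letter-probability matrix: alphabet= 4 w= 9 nsites= 20 E= 0
 0.020000 0.480000 0.480000 0.020000
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.480000 0.020000 0.020000 0.480000
 0.480000 0.020000 0.480000 0.020000

MOTIF DPE
letter-probability matrix: alphabet= 4 w= 6 nsites= 20 E= 0
 0.480000 0.020000 0.480000 0.020000
 0.013333 0.013333 0.960000 0.013333
 0.480000 0.020000 0.020000 0.480000
 0.020000 0.480000 0.020000 0.480000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000

MOTIF MTE
letter-probability matrix: alphabet= 4 w= 12 nsites= 20 E= 0
 0.013333 0.960000 0.013333 0.013333
 0.020000 0.480000 0.480000 0.020000
 0.960000 0.013333 0.013333 0.013333
 0.480000 0.020000 0.480000 0.020000
 0.013333 0.960000 0.013333 0.013333
 0.020000 0.480000 0.480000 0.020000
 0.020000 0.480000 0.480000 0.020000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.020000 0.480000 0.480000 0.020000

MOTIF M1BP
letter-probability matrix: alphabet= 4 w= 10 nsites= 20 E= 0
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.960000 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.960000 0.013333

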