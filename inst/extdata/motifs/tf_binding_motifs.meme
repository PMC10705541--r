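# Consensus-derived reconstructions (IUPAC consensus -> probabilities); synthetic, not experimentally fitted matrices.
MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF tf_core
letter-probability matrix: alphabet= 4 w= 7 nsites= 20 E= 0
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.250000 0.250000 0.250000 0.250000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000

MOTIF tf_motif_one
letter-probability matrix: alphabet= 4 w= 10 nsites= 20 E= 0
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333

MOTIF tf_motif_two
letter-probability matrix: alphabet= 4 w= 10 nsites= 20 E= 0
 0.480000 0.020000 0.480000 0.020000
 0.480000 0.020000 0.020000 0.480000
 0.480000 0.480000 0.020000 0.020000
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.320000 0.320000 0.320000 0.040000

MOTIF tf_motif_three
letter-probability matrix: alphabet= 4 w= 10 nsites= 20 E= 0
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.013333 0.960000

MOTIF tf_motif_four
letter-probability matrix: alphabet= 4 w= 9 nsites= 20 E= 0
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.020000 0.480000 0.480000 0.020000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333

MOTIF tf_selex
letter-probability matrix: alphabet= 4 w= 9 nsites= 20 E= 0
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.250000 0.250000 0.250000 0.250000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000

MOTIF tf_footprint
letter-probability matrix: alphabet= 4 w= 9 nsites= 20 E= 0
 0.013333 0.013333 0.013333 0.960000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000
 0.960000 0.013333 0.013333 0.013333
 0.960000 0.013333 0.013333 0.013333
 0.013333 0.960000 0.013333 0.013333
 0.250000 0.250000 0.250000 0.250000
 0.013333 0.013333 0.960000 0.013333
 0.013333 0.013333 0.013333 0.960000

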