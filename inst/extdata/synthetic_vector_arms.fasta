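>vector_arm_left synthetic stand-in for a cloning-vector left arm
CAAGTGACACGATATTTACGTAAGTAACCCCCTTAGCTTACCCCATCCCAAAATTTGGACAGGAACCTGAGGTGCACTTTGGAAGGACTCAAACGGACAGATGAGCGCCTTAGCCGGGCATCCCACTATATCGCTCCGTG
>vector_arm_right synthetic stand-in for a cloning-vector right arm
TATATCGAGTCATTCGTTGGACTACGCATCTCCATGCGGCAAGATAGCGCAAGGTGAGACTTGTGCGCGTGCATGATTTGCTAGCTGCCCCTTGCAACTTTATCAGAATTCACGCGCTCCTGCCATTGAGAGTTCCCAGG
>adaptor_1 synthetic stand-in for an SSH adaptor/nested-primer sequence
CAGCCTACGTACAGAGATGAGACCACGCACCGGCATAAGCCCCC
>adaptor_2 synthetic stand-in for an SSH adaptor/nested-primer sequence
TATAGTCAATAGTCCGTGTGCAAGAGGGAGAGTTAAGTGCCG
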