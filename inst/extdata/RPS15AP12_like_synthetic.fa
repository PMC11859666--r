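>RPS15AP12_like_synthetic planted 118-aa ORF; synthetic stand-in, not the real transcript
TCAGAAGCCCCATTCGCCATAATTCCTGAGTGTGCGGAGTGCTCACACGTTTTTACTTGG
ATGCCCATAGTGGAGGGCACGAAAGCACGGCGTGCCAGACGGCATAAGGCCTGTCCTGAA
ACTTGTGACGAACTGAAGTACCTTTACGCGACCACCTGTACCTCTGAACGGGTGAGAATA
AGTATTTGGTTGCTCTCTCTCCGCCCGCAGTGCGTCCTTTTTGAGGAGAGAGAACTGTGG
GGCACGGGCTGCATTAGCACTTGTCTGACCCGGACAAGGGCTGGTTCACGGCATTTACGT
CAGCCTTTTCGGCGTCCACAACTAGCCCCCTTACTGCAACCGCCGGCAATTCTACACGAT
ATCAAACCAGCAGGAACTTACTCATCAAAGCCTGGCTGGTTCGGGTCTGCGTACTAACGG
GTCGAGCTACTACCCATCCACAATATGAACATTATTCTTGGGCATAGGGGTCCACGCAGG
AAACGGGACAGAGGGTCTGGATATGGGCGGGTATGCTATATCACATCTCAAGTACTT
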