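class	motif
M1	TTGACCCGCCCCTGCTAGCAGGGGCGGGTCAA
M2	TGCCTGTTGCGTCACATGTGACGCAACAGGCA
M3	GCGAGGTCGCGTCTACGTAGACGCGACCTCGC
M4	TCGGGCGCCGGCCTCCGGAGGCCGGCGCCCGA
M5	AGGACGGGGCGCGGCGCGCCGCGCCCCGTCCT
M6	CGGCCCGGGGCGGTTCGAACCGCCCCGGGCCG
M7	GCCCCGGGTTCCCGCATGCGGGAACCCGGGGC
M8	CCCCGGCAGCCCCGTTAACGGGGCTGCCGGGG
M9	GCTCCTACAGCCGGCCGGCCGGCTGTAGGAGC
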