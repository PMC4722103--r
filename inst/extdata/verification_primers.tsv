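primer	amplicon_bp	forward	reverse
1	417	CTCCTTTTGCGAGGGGAACT	AAGAAACGATGCGAGGTGGT
2	892	CAAATCGCCTAAATGAATGTCCT	CATACCAGTCGCCAGTCCAA
3	605	GGGTAAAACCGCTGGGAGAG	CAGCGGTGTCAAACGCATTA
4	948	TTTCTGTTGCTTACGGGCGA	TGAGTGGAACTTGGAACGCA
5	421	GACCTATCGTCAGGGCAAGG	TAGGAGCGGAAGAAAAGGGG
6	581	ACTTTGGTGAATAGAGCGTTGA	GATAAGGCGTGAGGGTGCTT
7	840	TGCTTATGGCGGACAACCTT	CGGTTTGTGCGTCCAAATCA
8	422	TATACCTGCGTTGGTTGCGT	TAGGTGAGGTAGGTGAGGCA
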