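virophage	amplicon_bp	forward	reverse
Sputnik	534	CTACTACTGCTAGAATTACTGGTGT	ATGCTCCAGAAAGAATACCCTGT
Mavirus	522	ACACCCCCAGAACTCGATAC	ACAACCTAAACCGCGAGACA
ALM	520	TCCGAATGAACCGCCAATAGA	GTTTTGCGTTATGGTTCGGC
OLV	479	AAAGATGGTCCGGCTTCGAG	CTGATGCTAGAGTCGGCACG
YSLV1	426	AGCCGTCGCAATAGTTCCAG	GAAGGTGGTTACGCTACCGA
YSLV2	417	CACCTTTCGTATTTGGCGACC	AGCGGAAGTCGCTTATTCCT
YSLV3	627	CGACCAAGACTTCCAGCCTC	CACAAGTCCCACTGAGTTGC
YSLV4	513	CCATTTCTACCGACCCAGCA	GCACACGAGCGCAAATAAGA
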