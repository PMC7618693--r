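class_label	fwd	rev
CP	GCTACATGACTGCGCAGA	TGGGATACAATCTACTGG
APC	ACCCTGTGTGCTAGCACT	CATCAGGACGGAATCAAC
MFS	CAACCTTCCGCTTTCTGT	CCGATCGGTATCAGGGTA
DMT	GACATTTGTAGGCGTTGA	ATACAACGTGCAACCGCC
MATE	GGTGATGCAGGAAACCCA	GCCCAAACGGTGGATTGA
ABC	GCGAGCTATTGAAAGTTG	TCGGTATCAGGATTCATG
PA	CTGTCTCAGTGATATCGA	CCTTGACTCTCGAACGCA
UF	GCGGGATAGTTGGGGTTA	GACAAAAGGGTCAAACGT
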