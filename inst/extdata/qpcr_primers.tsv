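name	forward	reverse	refseq	product_size
AREG	tgtcgctcttgatactcggc	aggcatttcactcacagggg	NM_001657	173
LIF	gccacccatgtcacaacaac	gccacatagcttgtccaggt	NM_002309	140
LILRA5	cacgtgcaggcagggaa	ctgtgtgtcccagggttctg	NM_021250;NM_181879	159
NAMPT	ggagcatctgctcacttggt	tcatggtctttcccccaagc	NM_005746	155
PER3	atggcagtgagagcagtcct	aatcccatggacagtgtgct	NM_001289862;NM_001289861;NM_001289863;NM_016831;NM_001289864;NM_001377276;NM_001377275	157;211
B2M	tgggtttcatccatccgaca	acggcaggcatactcatctt	NM_004048	160
RPL19	caggcacatgggcataggtaa	ttcaccttcaggtacaggct	NM_000981;NM_001330200	165
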