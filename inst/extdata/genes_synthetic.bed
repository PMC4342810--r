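# Synthetic gene placements on the scaled 3 x 10 Mb test genome.
chr1	1000000	1100000	CCND1
chr1	3000000	3080000	ERBB2
chr1	5000000	5050000	MYC
chr1	7500000	7600000	FGFR1
chr2	500000	520000	TP53
chr2	2500000	2600000	PTEN
chr2	4800000	4900000	MDM4
chr2	7000000	7050000	AKT2
chr3	1500000	1600000	NKX2-1
chr3	4000000	4100000	AURKA
chr3	6500000	6550000	AR
chr3	8800000	8900000	EGFR
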