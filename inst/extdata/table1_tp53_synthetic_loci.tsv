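# TP53 mutations in eight hyperhaploid myeloma samples: protein changes and
# VAFs as published; genomic positions are SYNTHETIC placeholders inside the
# TP53 locus (the source table prints cDNA positions only). 1-based coords.
sample	gene	chrom	pos	protein_change	vaf
13875	TP53	17	7673700	E287fs	0.92
17188	TP53	17	7676250	V73fs	0.96
24138	TP53	17	7675900	LGFL111-114L	0.42
27082	TP53	17	7670650	F338fs	0.95
27647	TP53	17	7673802	R273H	0.92
35652	TP53	17	7674220	G244D	0.59
MMRF_1364	TP53	17	7673660	K292fs	0.96
MMRF_1499	TP53	17	7675150	F134S	0.89
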