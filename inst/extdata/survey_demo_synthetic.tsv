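genome_id	species	size_bp	rrna_operons	trna_genes	candidatus	free_living
LSE_001	Limosilactobacillus synthetica	1298316	7	61	0	1
CAND_01	Candidatus Minimus parvus	159662	1	20	1	0
LDB_A	Lactobacillus demo	1856951	9	65	0	1
LDB_B	Lactobacillus demo	2195000	9	70	0	1
STR_01	Streptococcus fictus	2100000	7	60	0	1
BAC_01	Bacillus exemplaris	4200000	13	86	0	1
ECO_01	Escherichia demo	4600000	7	89	0	1
PSE_01	Pseudomonas ficta	6300000	4	67	0	1
SYM_01	Buchnera symbiotica	640000	3	32	0	0
THE_01	Thermus exemplum	2030000	6	48	0	1
VIB_01	Vibrio velox	3100000	10	67	0	1
CAND_02	Candidatus Parvus minor	200000	1	18	1	0
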