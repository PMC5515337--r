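lesion_id	gene	protein_change	cdna_change	chrom	pos	ref_allele	alt_allele	alt_count	depth	is_promoter
FA1	MED12	Gly44Cys	c.130G>T	chrX	70339229	G	T	260	1040	FALSE
FA2	MED12	Gly44Val	c.131G>T	chrX	70339230	G	T	135	1000	FALSE
FA2	FGFR2	Ser252Trp	c.755C>G	chr10	123279677	G	C	300	1000	FALSE
FA2	KDM6A	Val1207Gly	c.3620T>G	chrX	44938563	T	G	295	1002	FALSE
FA2	KMT2D	Gln4347fs	c.13039del	chr12	49426000	AG	A	310	980	FALSE
FA3	MED12	Gly44Asp	c.131G>A	chrX	70339230	G	A	270	1080	FALSE
FA3	CCND2	Pro281Leu	c.842C>T	chr12	4382800	C	T	80	1067	FALSE
BenignPT	MED12	Gly44Val	c.131G>T	chrX	70339230	G	T	210	1050	FALSE
MalignantPT	MED12	Gly44Asp	c.131G>A	chrX	70339230	G	A	320	1065	FALSE
MalignantPT	TERT	.	c.-124C>T	chr5	1295228	G	A	290	950	TRUE
MalignantPT	SETD2	Arg1625Cys	c.4873C>T	chr3	47162000	G	A	305	1010	FALSE
MalignantPT	SETD2	Ser2111fs	c.6332del	chr3	47125000	TC	T	110	1048	FALSE
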