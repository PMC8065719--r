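target_id	chrom	pos	ref	alt	vclass	gene
EGFR_1	chr7	55242460	A	G	SNV	EGFR
EGFR_2	chr7	55259335	G	A	SNV	EGFR
KRAS_1	chr12	25398242	C	G	SNV	KRAS
KRAS_2	chr12	25380261	C	A	SNV	KRAS
TP53_1	chr17	7577543	A	T	SNV	TP53
TP53_2	chr17	7578298	G	C	SNV	TP53
PIK3CA_1	chr3	178936112	A	G	SNV	PIK3CA
PIK3CA_2	chr3	178952132	A	T	SNV	PIK3CA
FGFR3_1	chr4	1803624	T	A	SNV	FGFR3
FGFR3_2	chr4	1806205	G	A	SNV	FGFR3
BRAF_1	chr7	140453176	G	T	SNV	BRAF
NRAS_1	chr1	115256552	A	G	SNV	NRAS
ALK_1	chr2	29443691	T	C	SNV	ALK
MET_1	chr7	116412130	T	A	SNV	MET
ERBB2_1	chr17	37881005	C	G	SNV	ERBB2
IDH1_1	chr2	209113106	T	A	SNV	IDH1
KIT_1	chr4	55599361	TA	GC	MNP	KIT
PDGFRA_1	chr4	55152155	CG	GT	MNP	PDGFRA
APC_1	chr5	112175353	C	CTT	INS	APC
PTEN_1	chr10	89692825	CTCA	C	DEL	PTEN
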