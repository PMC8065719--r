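primer_id	sequence	segment_id	insert_offset
pr_EGFR_1	AGGAAGAAGCTATACGCTGGAA	seg_EGFR_1	22
pr_EGFR_2	CGGACATGAGTATTCTCTTCTG	seg_EGFR_2	22
pr_KRAS_1	GTTCCCTTGCCGCGACTCGGATAT	seg_KRAS_1	24
pr_KRAS_2	TGTTACCTCGGAGTACACCGCT	seg_KRAS_2	22
pr_TP53_1	TTCCGTCCCGCACTTGGCAGCATC	seg_TP53_1	24
pr_TP53_2	GATACTTTAACATCTTATCGAAGA	seg_TP53_2	24
pr_PIK3CA_1	AGTGCGTAAGGTCCAGGCGAGT	seg_PIK3CA_1	22
pr_PIK3CA_2	CACATAAGATGCCTTTACGTTG	seg_PIK3CA_2	22
pr_FGFR3_1	CAGCATTCCCACTAACAAGGCGAG	seg_FGFR3_1	24
pr_FGFR3_2	ATCGTCAGCATAAATCGTTGAAGT	seg_FGFR3_2	24
pr_BRAF_1	CAACAATACAAATTTATATGAA	seg_BRAF_1	22
pr_NRAS_1	CATGCAGCTATTCCGTCAAGCTC	seg_NRAS_1	23
pr_ALK_1	TCCTTTCGGCGCACGAAACGTCG	seg_ALK_1	23
pr_MET_1	CTGAATGATCCGAATTCACAAT	seg_MET_1	22
pr_ERBB2_1	ATTAGTGTCATAGGCCAACTATCG	seg_ERBB2_1	24
pr_IDH1_1	AGCATGCGTGAGCGGTGTTAGG	seg_IDH1_1	22
pr_KIT_1	ATGGATCGCCAACCGGCCTGGGTT	seg_KIT_1	24
pr_PDGFRA_1	GAGCACCCTGGGGAGGGGGTGCA	seg_PDGFRA_1	23
pr_APC_1	TCTTTACGTGAATAGTTGCGGAT	seg_APC_1	23
pr_PTEN_1	TTCGCCTACTGATTAAAATACTGT	seg_PTEN_1	24
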