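triplet	helix	fwd_printed	fwd_ndn	rev_printed	rev_ndn	rev_seq_corrected	note
GAA	QSGNLAR	CaaTCGGgTaacCTTgCCCGCCATATCCG	7	GGCGGGCAAGgTTAcCCGAttGACTGAAG	4	.	.
GAC	DRSNLTR	gaCagGagTaatCTTACCCGCCATATCCG	9	GGCGGGtAAGATTActCcTGtcACTGAAG	6	.	published reverse count 6 understates the recomputed distance 7
GAG	RSDNLAR	CGCTCGGATaatCTTgCCCGCCATATCCG	4	GGCGGGCAAGATTATCCGAGCGACTGAAG	0	.	.
GAT	TSGNLVR	acCTCGGgTaatCTTgtCCGCCATATCCG	8	GGCGGaCAAGATTAcCCGAGgaACTGAAG	4	.	reverse primer as published encodes Ser at helix position 1 (annotated Thr)
GCA	QSGDLTR	CaaTCGGgTGatCTTACCCGCCATATCCG	5	GGCGGGtAAGATcAcCCGAttGACTGAAG	4	.	published reverse count 4 understates the recomputed distance 5
GCC	DCRDLAR	gaCTGcagaGacCTTgCCCGCCATATCCG	9	GGCGGGCAAGgTctctgcAGtaACTGAAG	9	.	published forward count 9 understates the recomputed distance 10; reverse primer as published encodes Tyr at helix position 1 (annotated Asp)
GCG	RSDDLQR	CGCTCGGATGacCTTcaaCGCCATATCCG	5	GGCGttgAAGgTcATCCGAGCGACTGAAG	5	.	.
GGA	QSGHLQR	CagTCGGgTcatCTTcaaCGCCATATCCG	9	GGCGttgAAGATgAcCCGActGACTGAAG	7	.	.
GGG	RSDHLSR	CGCTCGGATcacCTTtCCCGCCATATCCG	4	GGCGGGaAAGgTgATCCGAGCGACTGAAG	3	.	.
GGT	TSGHLVR	acCTCGGgTcacCTTgtCCGCCATATCCG	8	GGCGGaCAAGgTgAcCCGAGgtACTGAAG	6	.	.
GTC	DPGALVR	gaCcCGGgTGCGCTTgtCCGCCATATCCG	6	GGCGGaCAAGcgcAtCCGgGtcACTGAAG	8	GGCGGACAAGCGCACCCGGGTCACTGAAG	published reverse sequence is inconsistent with its own count and mask; t15c restores count 8, the mask, and the Gly3 codon
GTG	RSDALTR	CGCTCGGATGCGCTTACCCGCCATATCCG	0	GGCGGGtAAGcgcATCCGAGCGACTGAAG	4	.	.
GTT	TSGSLVR	acCTCGGgTtCGtTagtCaGaCATATCCG	10	GtCtGaCtAacgaATCCGAGgtACTGAAG	10	.	reverse primer as published retains the template Asp codon at helix position 3 (annotated Gly)
AAG	RKDNLKN	CGCaaGGATaacCTTAaaaaCCATATCCG	9	GGtttttAAGgTTATCCttGCGACTGAAG	8	.	.
ACT	THLDLIR	acCcacctTGatCTTAtCCGCCATATCCG	10	GGCGGatAAGATcAaggtgGgtACTGAAG	10	.	.
AGA	QLAHLRA	CaaTtGGcTcacCTTcgCgcCCATATCCG	11	GGgcGcgAAGgTgAgCCaAttGACTGAAG	10	.	.
AGG	RSDHLTN	CGCTCGGATcacCTTACCaaCCATATCCG	5	GGttGGtAAGgTgATCCGAGCGACTGAAG	5	.	.
ATG	RRDELNV	CGCcgGGATGaGCTTAACgtCCATATCCG	5	GGacGttAAGcTcATCCcgGCGACTGAAG	8	.	published forward count 5 understates the recomputed distance 6
CTG	RNDALTE	CGCaatGAcGCGCTTACCgaaCATATCCG	7	GttcGGtAAGcgcgTCattGCGACTGAAG	11	.	.
TGA	QAGHLAS	CaagCGGgTcatCTTgCCaGCCATATCCG	9	GGCtGGCAAGATgAcCCGcttGACTGAAG	6	.	.
TGG	RSDHLTT	CGCagtGATcacCTTACCacCCATATCCG	8	GGgtGGtAAGgTgATCactGCGACTGAAG	8	.	.
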