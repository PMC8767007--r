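module	nodes	edges	seed_genes
Module 1	133	8061	RPL13,RPLP0,RPS2,RPS24
Module 5	44	231	MYC,COX7B,SOCS3
Module 6	36	126	MAP2K3,TNFSF10
Module 7	6	14	PER3
Module 8	25	67	IRAK3
Module 9	30	80	BCL6,HSPB1
Module 10	16	38	ENO1
Module 11	5	10	ATP1A1
Module 13	5	6	LYN,FCGR3A
Module 15	3	3	NPR3,NPPB
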