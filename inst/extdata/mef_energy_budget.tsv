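class	expr_pct_WT	expr_pct_G12D	expr_pct_G12V	expr_pct_Q61L	flux_WT	flux_G12D	flux_G12V	flux_Q61L
058_Nucelotide metabolism (ATP)	1.90	1.95	1.96	1.94	24.56	55.24	40.81	45.10
011_Cytoskeleton (ATP)	1.49	1.46	1.45	1.45	19.22	41.25	30.25	33.88
116_Glycosylation (ATP)	1.14	1.12	1.13	1.17	14.79	31.86	23.48	27.37
096_Chaperone (ATP)	1.02	1.09	1.07	1.07	13.13	30.76	22.27	25.04
084_Amino acid tRNA ligase (ATP)	0.97	1.03	1.03	1.01	12.51	29.16	21.35	23.47
012_Cytoskeleton (GTP)	0.72	0.68	0.70	0.71	9.31	19.32	14.54	16.58
107_Protein kinases (ATP)	0.44	0.41	0.43	0.44	5.67	11.61	8.97	10.22
106_Vesicle trafficking (GTP)	0.44	0.43	0.42	0.39	5.64	12.18	8.73	9.16
027_Carbohydrate metabolism-other (ATP)	0.41	0.42	0.43	0.42	5.25	11.88	8.86	9.71
076_Metabolism of mRNA (ATP)	0.41	0.40	0.43	0.40	5.35	11.20	8.89	9.24
064_Metabolism of vitamins and cofactors (ATP)	0.37	0.40	0.38	0.36	4.79	11.25	7.85	8.29
016_Glycolysis and Gluconeogenesis (ATP)	0.31	0.32	0.32	0.32	4.05	9.14	6.75	7.41
131_Chromatin organization (ATP)	0.31	0.29	0.30	0.33	4.06	8.35	6.30	7.59
006_Receptor kinase (ATP)	0.35	0.28	0.32	0.28	4.49	7.80	6.67	6.55
009_Transporter ions (ATP)	0.29	0.26	0.30	0.30	3.77	7.33	6.28	6.94
020_Citric acid and TCA cycle (ATP)	0.27	0.27	0.27	0.27	3.43	7.59	5.61	6.22
136_DNA replication (ATP)	0.28	0.24	0.28	0.28	3.66	6.80	5.74	6.52
102_Protein secretion (ATP)	0.21	0.22	0.22	0.22	2.69	6.20	4.57	5.23
068_Transporter other (ATP)	0.21	0.23	0.22	0.21	2.70	6.46	4.57	4.88
103_Protein secretion (GTP)	0.23	0.21	0.20	0.21	2.92	6.03	4.18	4.80
042_Phospholipid metabolism (ATP)	0.18	0.18	0.19	0.19	2.26	5.20	3.88	4.37
070_G protein (GTP)	0.21	0.15	0.17	0.17	2.72	4.12	3.64	3.92
052_Metabolism of amino acids (ATP)	0.16	0.17	0.18	0.16	2.05	4.79	3.66	3.67
155_Ras GTPases (GTP)	0.18	0.15	0.15	0.15	2.30	4.36	3.13	3.55
081_Metabolism of tRNA (ATP)	0.14	0.16	0.16	0.15	1.80	4.59	3.32	3.56
118_Ubiquitination-activation-E1s (ATP)	0.15	0.16	0.15	0.15	1.91	4.49	3.03	3.50
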