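clinical_area	gene	inheritance	n_lt_0.005	n_0.005_0.01	n_0.01_0.05	n_0.05_0.1	n_ge_0.1
hereditary_cancer	APC	dominant	6	0	0	0	0
hereditary_cancer	ATM	recessive	104	1	0	0	0
hereditary_cancer	BARD1	dominant	22	0	0	0	0
hereditary_cancer	BLM	recessive	38	2	1	0	0
hereditary_cancer	BMPR1A	dominant	3	1	0	0	0
hereditary_cancer	BRCA1	dominant	67	0	2	0	0
hereditary_cancer	BRCA2	dominant	103	2	1	0	0
hereditary_cancer	BRIP1	recessive	32	0	1	0	0
hereditary_cancer	CDH1	dominant	5	0	0	0	0
hereditary_cancer	CDKN2A	dominant	4	0	0	0	0
hereditary_cancer	CHEK2	dominant	29	3	2	0	1
hereditary_cancer	CTRC	dominant	11	1	0	0	0
hereditary_cancer	EPCAM	recessive	9	1	0	0	0
hereditary_cancer	FANCC	recessive	23	1	0	0	0
hereditary_cancer	MEN1	dominant	0	0	0	0	0
hereditary_cancer	MLH1	dominant	5	0	0	0	0
hereditary_cancer	MRE11A	recessive	18	1	0	0	0
hereditary_cancer	MSH2	dominant	7	1	0	0	0
hereditary_cancer	MSH6	dominant	25	0	1	0	0
hereditary_cancer	MUTYH	recessive	19	3	2	0	1
hereditary_cancer	NBN	recessive	33	1	1	0	0
hereditary_cancer	NF1	dominant	23	1	0	0	0
hereditary_cancer	PALB2	dominant	35	2	1	0	0
hereditary_cancer	PMS2	dominant	32	0	0	0	0
hereditary_cancer	PTCH1	dominant	2	0	0	0	0
hereditary_cancer	PTEN	dominant	2	0	0	0	0
hereditary_cancer	RAD50	recessive	42	2	3	0	0
hereditary_cancer	RAD51C	recessive	19	3	0	0	0
hereditary_cancer	SMAD4	dominant	2	0	0	0	0
hereditary_cancer	SPINK1	dominant	1	0	1	0	0
hereditary_cancer	STK11	dominant	0	0	0	0	0
hereditary_cancer	TP53	dominant	1	0	0	0	0
hereditary_cancer	VHL	dominant	0	0	0	0	0
primary_ciliary_dyskinesia	ARMC4	recessive	36	3	0	0	0
primary_ciliary_dyskinesia	C21orf59	recessive	7	1	1	0	0
primary_ciliary_dyskinesia	CCDC103	recessive	3	0	0	0	0
primary_ciliary_dyskinesia	CCDC114	recessive	6	0	0	0	0
primary_ciliary_dyskinesia	CCDC151	recessive	16	1	0	0	0
primary_ciliary_dyskinesia	CCDC39	recessive	22	2	0	0	0
primary_ciliary_dyskinesia	CCDC40	recessive	32	1	1	0	0
primary_ciliary_dyskinesia	CCDC65	recessive	17	0	1	0	0
primary_ciliary_dyskinesia	CCNO	recessive	0	0	0	0	0
primary_ciliary_dyskinesia	DNAAF1	recessive	19	2	1	0	0
primary_ciliary_dyskinesia	DNAAF2	recessive	12	0	0	0	0
primary_ciliary_dyskinesia	DNAAF3	recessive	16	2	1	0	0
primary_ciliary_dyskinesia	DNAH11	recessive	80	1	2	0	0
primary_ciliary_dyskinesia	DNAH5	recessive	113	0	2	0	0
primary_ciliary_dyskinesia	DNAI1	recessive	15	0	1	0	0
primary_ciliary_dyskinesia	DNAI2	recessive	21	1	1	0	0
primary_ciliary_dyskinesia	DNAL1	recessive	3	0	0	0	0
primary_ciliary_dyskinesia	DRC1	recessive	22	0	2	0	0
primary_ciliary_dyskinesia	DYX1C1	recessive	18	1	0	0	0
primary_ciliary_dyskinesia	RPGR	recessive	1	0	0	0	0
primary_ciliary_dyskinesia	RSPH1	recessive	9	1	2	0	0
primary_ciliary_dyskinesia	RSPH4A	recessive	27	1	0	0	0
primary_ciliary_dyskinesia	RSPH9	recessive	4	0	0	0	0
primary_ciliary_dyskinesia	SPAG1	recessive	21	2	0	0	0
primary_ciliary_dyskinesia	ZMYND10	recessive	16	0	0	0	0
cardiomyopathy_arrhythmia	BAG3	dominant	2	0	0	0	0
cardiomyopathy_arrhythmia	CACNA1C	dominant	6	0	0	0	0
cardiomyopathy_arrhythmia	CASQ2	recessive	15	0	0	0	0
cardiomyopathy_arrhythmia	DES	recessive	5	0	0	0	0
cardiomyopathy_arrhythmia	DSC2	dominant	13	0	0	0	0
cardiomyopathy_arrhythmia	DSG2	dominant	19	0	0	0	0
cardiomyopathy_arrhythmia	DSP	recessive	21	0	0	0	0
cardiomyopathy_arrhythmia	FHL1	dominant	0	0	0	0	0
cardiomyopathy_arrhythmia	HCN4	dominant	5	0	0	0	0
cardiomyopathy_arrhythmia	JUP	recessive	7	0	0	0	0
cardiomyopathy_arrhythmia	KCNE1	dominant	0	0	0	0	0
cardiomyopathy_arrhythmia	KCNH2	dominant	5	0	2	0	0
cardiomyopathy_arrhythmia	KCNQ1	dominant	15	0	1	0	0
cardiomyopathy_arrhythmia	LAMP2	dominant	0	0	0	0	0
cardiomyopathy_arrhythmia	LMNA	dominant	1	0	0	0	0
cardiomyopathy_arrhythmia	MYBPC3	dominant	17	0	0	0	0
cardiomyopathy_arrhythmia	NKX2-5	dominant	1	0	0	0	0
cardiomyopathy_arrhythmia	PKP2	dominant	18	0	1	0	0
cardiomyopathy_arrhythmia	PLN	dominant	0	0	0	0	0
cardiomyopathy_arrhythmia	SCN5A	dominant	9	0	0	0	0
cardiomyopathy_arrhythmia	TRDN	recessive	6	1	2	0	0
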