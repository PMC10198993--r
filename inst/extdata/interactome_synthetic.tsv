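protein1	protein2	combined_score
ATM	TP53	0.95
ATM	CHEK2	0.95
ATM	CHEK1	0.95
ATM	APEX1	0.95
ATM	NBN	0.95
TP53	CHEK2	0.95
TP53	CHEK1	0.95
TP53	APEX1	0.95
TP53	NBN	0.95
CHEK2	CHEK1	0.95
CHEK2	APEX1	0.95
CHEK2	NBN	0.95
CHEK1	APEX1	0.95
CHEK1	NBN	0.95
APEX1	NBN	0.95
ATM	PCNA	0.95
ATM	TP53BP1	0.95
ATM	MCM6	0.95
ATM	CDT1	0.95
PCNA	TP53BP1	0.95
PCNA	MCM6	0.95
PCNA	CDT1	0.95
TP53BP1	MCM6	0.95
TP53BP1	CDT1	0.95
MCM6	CDT1	0.95
TP53	MAPK1	0.9
TP53	PIN1	0.9
CHEK2	PIM1	0.9
CHEK1	TDP1	0.9
NBN	POLH	0.9
PCNA	POLH	0.9
PCNA	GMNN	0.9
TP53BP1	TDP1	0.9
MCM6	GMNN	0.9
CDT1	GMNN	0.9
DUSP6	MAPK1	0.9
DUSP6	PIM1	0.9
RPS6KA1	MAPK1	0.9
RPS6KA1	PIN1	0.9
CYP1A1	CYP1A2	0.85
CYP1A1	CYP1B1	0.85
CYP1A1	CYP2C19	0.85
CYP1A1	CYP2D6	0.85
CYP1A1	CYP3A4	0.85
CYP1A2	CYP1B1	0.85
CYP1A2	CYP2C19	0.85
CYP1A2	CYP2D6	0.85
CYP1A2	CYP3A4	0.85
CYP1B1	CYP2C19	0.85
CYP1B1	CYP2D6	0.85
CYP1B1	CYP3A4	0.85
CYP2C19	CYP2D6	0.85
CYP2C19	CYP3A4	0.85
CYP2D6	CYP3A4	0.85
ADORA3	MAPK1	0.524
MAPK1	POLH	0.544
GMNN	TAS2R31	0.528
APEX1	KDM4E	0.693
KDM4E	TAS2R31	0.76
ABCG2	CYP1A1	0.761
TAS2R31	VDR	0.558
ADORA3	CBX1	0.714
CYP3A4	VDR	0.772
PIM1	POLH	0.589
CYP1B1	TARDBP	0.606
CYP3A4	POLH	0.708
CBX1	CYP3A4	0.526
CYP2C19	TAS2R31	0.719
CBX1	PIN1	0.676
MEN1	PIM1	0.655
ALDH1A1	VDR	0.625
CYP1B1	PIM1	0.739
PIM1	TDP1	0.515
MAPK1	TDP1	0.742
ALDH1A1	RGS4	0.741
TARDBP	VDR	0.765
TDP1	VDR	0.71
APEX1	CBX1	0.528
CYP2D6	KDM4E	0.662
ADORA3	TAS2R31	0.677
ABCG2	MEN1	0.772
ALDH1A1	CYP1B1	0.743
POLH	TARDBP	0.651
APEX1	TARDBP	0.675
CYP1A2	TDP1	0.743
PIM1	TAS2R31	0.52
MEN1	PIN1	0.754
CYP2C19	MEN1	0.686
CYP2D6	MAPK1	0.55
ABCG2	GMNN	0.552
PIN1	RGS4	0.797
CYP1A2	GMNN	0.704
ADORA3	CYP1A1	0.738
CYP2D6	PIN1	0.627
GMNN	MAPK1	0.643
ADORA3	TARDBP	0.504
ABCG2	TARDBP	0.654
RGS4	TARDBP	0.588
ALDH1A1	ATXN2	0.78
ATXN2	TDP1	0.779
KDM4E	TDP1	0.759
ALDH1A1	POLH	0.751
KDM4E	RGS4	0.657
ABCG2	ATXN2	0.719
ADORA3	ALDH1A1	0.651
CBX1	GMNN	0.581
ALDH1A1	MEN1	0.767
ATXN2	PIN1	0.529
ABCG2	KDM4E	0.788
PIN1	TAS2R31	0.507
FILL1	CYP1A1	0.45
FILL2	CYP1A2	0.45
FILL3	CYP2C19	0.45
FILL4	CYP2D6	0.45
FILL5	CYP3A4	0.45
FILL6	ADORA3	0.45
FILL7	ALDH1A1	0.45
FILL8	ATXN2	0.45
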