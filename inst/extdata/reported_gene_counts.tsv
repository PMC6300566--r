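gene	Schizophrenia	Bipolar	AD	ALS	FTLD	Prion	MDD	Sum
MAPK3	0	0	4	0	1.33	4	4	13.33
APP	0	0	6	0	0	0	6	12
TP53	0	0	0	5	2.5	0	0	7.5
RAC1	0	0	0	4	2	0	0	6
PSEN1	0	0	4	0	2	0	0	6
PLCB3	0	0	3	0	0	0	3	6
PLCB2	0	0	3	0	0	0	3	6
PLCB1	0	0	3	0	0	0	3	6
PPP3CC	0	0	3	3	0	0	0	6
PRKACB	0	0	0	0	0	3	3	6
ITPR1	0	0	3	0	0	0	3	6
PPP3CA	0	0	3	3	0	0	0	6
PRKACG	0	0	0	0	0	3	3	6
NOS1	0	0	3	3	0	0	0	6
PLCB4	0	0	3	0	0	0	3	6
PRKACA	0	0	0	0	0	3	3	6
CYCS	0	0	3	3	0	0	0	6
HTR2A	1	2	0	0	0	0	2	5
NOTCH1	0	0	0	0	0	5	0	5
GAPDH	0	0	5	0	0	0	0	5
MAP2K1	0	0	0	0	0.67	2	2	4.67
BAX	0	0	0	2	0.67	2	0	4.67
GRM1	1.5	3	0	0	0	0	0	4.5
TNF	0	0	2	2	0	0	0	4
GNAQ	0	0	2	0	0	0	2	4
GNG2	0	2	0	0	0	0	2	4
ITPR3	0	0	2	0	0	0	2	4
CDK5	0	0	4	0	0	0	0	4
FYN	0	0	0	0	0	4	0	4
IL1B	0	0	2	0	0	2	0	4
ITPR2	0	0	2	0	0	0	2	4
PRKCA	0	0	0	0	0	0	4	4
PPP3CB	0	0	2	2	0	0	0	4
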