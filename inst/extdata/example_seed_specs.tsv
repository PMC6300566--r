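BDNF	0.4	1
BPNT1	0.6	2
DISC1	0.8	2
DIXDC1	0.6	2
FBP1	0.9	2
GSK3A	0.4	1
GSK3B	0.4	1
IMPAD	0.9	2
INPP1	0.7	2
PGM1	0.4	1
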