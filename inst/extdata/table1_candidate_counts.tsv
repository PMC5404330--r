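gene	common	low_frequency	rare	novel	total
ATP2C2	2	2	2	0	6
AUTS2	1	0	1	0	2
CMIP	0	0	0	0	0
CNTNAP2	0	0	0	1	1
CNTNAP5	0	1	1	0	2
DCDC2	2	1	0	0	3
DOCK4	0	0	0	0	0
DYX1C1	0	0	0	0	0
ERC1	1	1	0	1	3
FOXP1	0	0	0	0	0
FOXP2	0	0	0	0	0
GRIN2A	0	0	0	1	1
GRIN2B	0	0	0	1	1
KIAA0319	4	2	0	0	6
NFXL1	1	0	0	0	1
ROBO1	0	1	1	0	2
SEMA6D	2	0	0	1	3
SETBP1	5	0	0	0	5
SRPX2	0	0	1	0	1
All	18	8	6	5	37
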