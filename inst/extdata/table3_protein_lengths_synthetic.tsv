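gene	stop_aa_pos	protein_length
OR6P1	266	317
SYNPR	31	196
IDO2	219	432
OXR1	5	174
MUC6	703	2439
OR52B2	243	323
NUDT16L1	186	192
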