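name	recognition	cut_offset	sensitivity
HaeIII	GGCC	2	insensitive
TaqI	TCGA	1	insensitive
PvuII	CAGCTG	3	insensitive
MspI	CCGG	1	blocked_by_outer_C
HpaII	CCGG	1	blocked_by_full_internal_C
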