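class	affected	healthy	one_tumor	multi_tumor	crc	ec	mean_age
point	54	53	36	18	45	15	42
LGR	16	11	10	6	15	3	43
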