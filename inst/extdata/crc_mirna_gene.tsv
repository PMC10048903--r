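hsa-miR-622	TP53	repress
hsa-miR-429	TP53	repress
hsa-miR-133b	EGFR	repress
hsa-miR-429	EGFR	repress
hsa-miR-133b	AKT1	repress
hsa-miR-429	JUN	repress
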