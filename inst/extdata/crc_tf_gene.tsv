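EZH2	TP53	repress
KLF4	TP53	repress
HDAC1	TP53	repress
AR	EGFR	activate
NFKB1	EGFR	activate
AR	AKT1	repress
HDAC4	JUN	repress
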