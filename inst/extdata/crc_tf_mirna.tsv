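KLF4	hsa-miR-429	activate
NFKB1	hsa-miR-429	activate
AR	hsa-miR-133b	activate
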