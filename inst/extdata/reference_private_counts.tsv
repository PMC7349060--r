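genotype	private_snps	private_indels
E7	93	29
E8	29	16
E17	288	55
E36	11	14
E37	11	23
E42	11050	1640
E45	99	41
E53	47	36
E76	76	20
E107	921	83
DOCET	51	57
JAG8810	186	99
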