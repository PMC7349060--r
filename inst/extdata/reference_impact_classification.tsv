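class	total	high	moderate	low	modifier	affected_genes
SNP	22594	15	239	252	22088	4124
InDel	3519	22	44	24	3429	1863
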