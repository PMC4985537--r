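snp_id	gene	effect_allele	other_allele	beta	trait	maf
rs1443512	HOXC13	A	G	0.028	WHR	0.24
rs4846567	LYPLAL1	G	T	0.034	WHR	0.28
rs1011731	DNM3-PIGC	G	A	0.028	WHR	0.43
rs9491696	RSPO3	G	C	0.042	WHR	0.48
rs6905288	VEGFA	A	G	0.036	WHR	0.44
rs984222	TBX15-WARS2	G	C	0.034	WHR	0.37
rs1055144	NFE2L3	T	C	0.030	WHR	0.21
rs10195252	GRB14	T	C	0.033	WHR	0.40
rs718314	ITPR2-SSPN	G	A	0.030	WHR	0.26
rs1294421	LY86	G	T	0.026	WHR	0.39
rs6861681	CPEB4	A	G	0.022	WHR	0.29
rs4823006	ZNRF3	A	G	0.024	WHR	0.47
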