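snp_id	gene	effect_allele	other_allele	beta	trait	maf
rs571312	MC4R	A	C	0.23	BMI	0.24
rs3810291	TMEM160	A	G	0.09	BMI	0.28
rs1555543	PTBP2	C	A	0.06	BMI	0.40
rs206936	NUDT3	G	A	0.06	BMI	0.21
rs987237	TFAP2B	G	A	0.13	BMI	0.18
rs4836133	ZNF608	A	C	0.07	BMI	0.48
rs2241423	MAP2K5	G	A	0.13	BMI	0.22
rs1558902	FTO	A	T	0.39	BMI	0.42
rs2867125	TMEM18	C	T	0.31	BMI	0.17
rs10938397	GNPDA2	G	A	0.18	BMI	0.43
rs10767664	BDNF	A	T	0.19	BMI	0.22
rs2815752	NEGR1	A	G	0.13	BMI	0.39
rs7359397	SH2B1	T	C	0.15	BMI	0.40
rs9816226	ETV5	T	A	0.14	BMI	0.18
rs3817334	MTCH2	T	C	0.06	BMI	0.41
rs29941	KCTD15	G	A	0.06	BMI	0.33
rs543874	SEC16B	G	A	0.22	BMI	0.19
rs7138803	FAIM2	A	G	0.12	BMI	0.38
rs10150332	NRXN3	C	T	0.13	BMI	0.21
rs12444979	GPRC5B	C	T	0.17	BMI	0.17
rs2287019	GIPR	C	T	0.15	BMI	0.20
rs1514175	TNNI3K	A	G	0.07	BMI	0.43
rs2112347	FLJ35779	T	G	0.10	BMI	0.37
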