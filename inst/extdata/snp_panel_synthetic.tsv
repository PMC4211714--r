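snp_id	risk_allele	trait	risk_allele_freq	locus
rs9939609	A	BMI	0.41	FTO
rs2867125	C	BMI	0.83	TMEM18
rs17782313	C	BMI	0.24	MC4R
rs10938397	G	BMI	0.43	GNPDA2
rs10767664	A	BMI	0.78	BDNF
rs2568958	A	BMI	0.62	NEGR1
rs7359397	T	BMI	0.40	SH2B1
rs7647305	C	BMI	0.79	ETV5
rs3817334	T	BMI	0.41	MTCH2
rs29941	G	BMI	0.67	KCTD15
rs543874	G	BMI	0.19	SEC16B
rs713586	C	BMI	0.47	RBJ
rs12444979	C	BMI	0.86	GPRC5B
rs2241423	G	BMI	0.78	MAP2K5
rs2287019	C	BMI	0.80	QPCTL
rs1514175	A	BMI	0.43	TNNI3K
rs13107325	T	BMI	0.07	SLC39A8
rs2112347	T	BMI	0.63	FLJ35779
rs10968576	G	BMI	0.31	LRRN6C
rs3810291	A	BMI	0.66	TMEM160
rs887912	T	BMI	0.29	FANCL
rs13078807	G	BMI	0.20	CADM2
rs11847697	T	BMI	0.04	PRKD1
rs2890652	C	BMI	0.18	LRP1B
rs1555543	C	BMI	0.59	PTBP2
rs4771122	G	BMI	0.24	MTIF3
rs4836133	A	BMI	0.48	ZNF608
rs4929949	C	BMI	0.52	RPL27A
rs206936	G	BMI	0.21	NUDT3
rs6602024	A	BMI	0.16	PFKP
rs987237	G	BMI+WC	0.18	TFAP2B
rs7138803	A	BMI+WC	0.38	FAIM2
rs10150332	C	BMI+WC	0.21	NRXN3
rs7826222	G	WC	0.18	MSRA
rs12970134	A	WC	0.27	MC4R_down
rs4788099	G	WC	0.36	SH2B1_region
rs9491696	G	WHR_BMI	0.52	RSPO3
rs6905288	A	WHR_BMI	0.56	VEGFA
rs984222	G	WHR_BMI	0.37	TBX15_WARS2
rs1055144	T	WHR_BMI	0.21	NFE2L3
rs10195252	T	WHR_BMI	0.60	GRB14
rs1011731	G	WHR_BMI	0.43	DNM3_PIGC
rs718314	G	WHR_BMI	0.26	ITPR2_SSPN
rs1294421	G	WHR_BMI	0.61	LY86
rs1443512	A	WHR_BMI	0.24	HOXC13
rs6795735	C	WHR_BMI	0.41	ADAMTS9
rs4823006	A	WHR_BMI	0.57	ZNRF3_KREMEN1
rs6784615	T	WHR_BMI	0.94	NISCH_STAB1
rs6861681	A	WHR_BMI	0.42	CPEB4
rs4846567	G	WHR_BMI	0.72	LYPLAL1
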