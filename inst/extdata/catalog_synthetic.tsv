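ec	name	cazy	mode	gene_name	uniprot	cbs_id	atcc_id	characterized	refs	ambiguous_probe_group
3.2.1.4	endo-1,4-β-D-glucanase	GH5;GH12	endo	eglA		SYN0001	SYNT0001	FALSE		
3.2.1.4	endo-1,4-β-D-glucanase	GH5;GH12	endo	eglB		SYN0002	SYNT0002	FALSE		
3.2.1.21	β-glucosidase	GH3	exo_nonreducing	bglA		SYN0003	SYNT0003	FALSE		
3.2.1.1	α-amylase	GH13	endo	amyA		SYN0004	SYNT0004	FALSE		amy
3.2.1.1	α-amylase	GH13	endo	amyB		SYN0005	SYNT0005	FALSE		amy
3.2.1.1	α-amylase	GH13	endo	amyP		SYN0006	SYNT0006	FALSE		amy
3.2.1.3	glucoamylase	GH15	exo_nonreducing	glaA		SYN0007	SYNT0007	FALSE		
3.2.1.20	α-glucosidase	GH31	exo_nonreducing	agdA		SYN0008	SYNT0008	FALSE		
3.2.1.41	pullulanase	GH13	endo	pulA		SYN0009	SYNT0009	FALSE		
3.2.1.7	endo-inulinase	GH32	endo	inuA		SYN0010	SYNT0010	FALSE		
3.2.1.80	exo-inulinase	GH32	exo_nonreducing	inuE		SYN0011	SYNT0011	FALSE		
3.2.1.78	endo-1,4-β-D-mannanase	GH5;GH26	endo	manA		SYN0012	SYNT0012	FALSE		
3.2.1.25	β-mannosidase	GH2	exo_nonreducing	mndB		SYN0013	SYNT0013	FALSE		
3.2.1.22	α-galactosidase	GH27;GH36	debranching	aglD		SYN0014	SYNT0014	FALSE		
3.2.1.23	β-galactosidase	GH35	exo_nonreducing	lacB		SYN0015	SYNT0015	FALSE		
3.2.1.8	endo-1,4-β-D-xylanase	GH10;GH11	endo	xlnB		SYN0016	SYNT0016	FALSE		
3.2.1.8	endo-1,4-β-D-xylanase	GH10;GH11	endo	xlnC		SYN0017	SYNT0017	FALSE		
3.2.1.37	β-xylosidase	GH3;GH43	exo_nonreducing	xlnD		SYN0018	SYNT0018	FALSE		
3.2.1.55	α-L-arabinofuranosidase	GH51;GH54	exo_nonreducing	abfA		SYN0019	SYNT0019	FALSE		
3.2.1.55	α-L-arabinofuranosidase	GH51;GH54	exo_nonreducing	abfB		SYN0020	SYNT0020	FALSE		
3.2.1.139	α-glucuronidase	GH67	debranching	aguA		SYN0021	SYNT0021	FALSE		
3.1.1.72	acetyl xylan esterase	CE1	esterase	axeA		SYN0022	SYNT0022	FALSE		
3.1.1.73	feruloyl esterase	CE1	esterase	faeA		SYN0023	SYNT0023	FALSE		
3.1.1.73	feruloyl esterase	CE1	esterase	faeB		SYN0024	SYNT0024	FALSE		
3.1.1.6	acetyl esterase	CE16	esterase	aceA		SYN0025	SYNT0025	FALSE		
3.2.1.15	endo-polygalacturonase	GH28	endo	pgaA		SYN0026	SYNT0026	FALSE		
3.2.1.15	endo-polygalacturonase	GH28	endo	pgaB		SYN0027	SYNT0027	FALSE		
3.2.1.67	exo-polygalacturonase	GH28	exo_nonreducing	pgxA		SYN0028	SYNT0028	FALSE		
3.2.1.173	rhamnogalacturonan galacturonohydrolase	GH28	exo_nonreducing	rgxA		SYN0029	SYNT0029	FALSE		
3.2.1.171	rhamnogalacturonan hydrolase	GH28	endo	rhgA		SYN0030	SYNT0030	FALSE		
3.2.1.40	α-L-rhamnosidase	GH78	exo_nonreducing	rhaA		SYN0031	SYNT0031	FALSE		
3.1.1.86	rhamnogalacturonan acetyl esterase	CE12	esterase	rgaeA		SYN0032	SYNT0032	FALSE		
3.1.1.11	pectin methylesterase	CE8	esterase	pmeA		SYN0033	SYNT0033	FALSE		
3.2.1.99	endo-1,5-α-L-arabinanase	GH43	endo	abnA		SYN0034	SYNT0034	FALSE		
3.2.1.89	endo-1,4-β-D-galactanase	GH53	endo	galA		SYN0035	SYNT0035	FALSE		
3.2.1.181	endo-1,3-β-D-galactanase	GH43	endo	galB		SYN0036	SYNT0036	FALSE		
3.2.1.177	α-xylosidase	GH31	debranching	axlA		SYN0037	SYNT0037	FALSE		
3.2.1.51	α-L-fucosidase	GH29	exo_nonreducing	afcA		SYN0038	SYNT0038	FALSE		
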