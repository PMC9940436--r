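analysis	trait	SNP	CHR	POS	GENE	EA	OA	EAF	BETA	SE	P	F	obesity_associated
primary	NAFLD	rs2068834	2	27839539	ZNF512	C	T	0.275	0.264	0.041	8.5e-11	42.1	yes
primary	NAFLD	rs13118664	4	88239609	HSD17B13	T	A	0.251	-0.302	0.053	1.4e-08	32.2	no
primary	NAFLD	rs17216588	19	19664077	CILP2	T	C	0.077	0.477	0.064	7.2e-14	56.0	no
primary	NAFLD	rs738409	22	44324727	PNPLA3	G	C	0.224	0.603	0.041	1.5e-49	219.1	no
primary	PCOS	rs7563201	2	43561780	THADA	A	G	0.450	-0.108	0.017	3.7e-10	39.5	no
primary	PCOS	rs2178575	2	213391766	ERBB4	A	G	0.150	0.166	0.022	3.3e-14	57.7	no
primary	PCOS	rs13164856	5	131813204	IRF1/RAD50	T	C	0.730	0.124	0.019	1.4e-10	40.9	no
primary	PCOS	rs804279	8	11623889	GATA4/NEIL2	A	T	0.260	0.128	0.018	3.8e-12	48.1	no
primary	PCOS	rs10739076	9	5440589	PLGRKT	A	C	0.310	0.110	0.020	2.5e-08	31.0	no
primary	PCOS	rs7864171	9	97723266	FANCC	A	G	0.430	-0.093	0.017	2.9e-08	30.8	no
primary	PCOS	rs9696009	9	126619233	DENND1A	A	G	0.070	0.202	0.031	8.0e-11	42.2	no
primary	PCOS	rs11031005	11	30226356	ARL14EP/FSHB	T	C	0.850	-0.159	0.022	8.7e-13	51.0	no
primary	PCOS	rs11225154	11	102043240	YAP1	A	G	0.090	0.179	0.027	5.4e-11	43.2	no
primary	PCOS	rs1784692	11	113949232	ZBTB16	T	C	0.820	0.144	0.023	1.9e-10	40.5	no
primary	PCOS	rs2271194	12	56477694	ERBB3/RAB5B	A	T	0.420	0.097	0.017	4.6e-09	34.2	no
primary	PCOS	rs1795379	12	75941042	KRR1	T	C	0.240	-0.117	0.020	1.8e-09	36.2	no
primary	PCOS	rs8043701	16	52375777	TOX3	A	T	0.820	-0.127	0.021	9.6e-10	37.5	no
replication	NAFLD	rs2807834	1	220970593	MARC1	T	G	0.309	-0.132	0.021	1.1e-10	41.7	no
replication	NAFLD	rs1260326	2	27730940	GCKR	T	C	0.388	0.132	0.019	4.0e-12	48.1	no
replication	NAFLD	rs17321515	8	126486409	TRIB1	G	A	0.473	-0.145	0.019	1.4e-14	59.2	no
replication	NAFLD	rs73001065	19	19460541	MAU2	C	G	0.068	0.327	0.034	1.7e-22	95.2	no
replication	NAFLD	rs429358	19	45411941	APOE	C	T	0.154	-0.202	0.027	5.3e-14	56.6	yes
replication	NAFLD	rs3747207	22	44324855	PNPLA3	A	G	0.215	0.340	0.022	3.5e-56	249.4	no
replication	PCOS	rs7564590	2	213387900	ERBB4	T	C	0.356	0.171	0.026	4.8e-11	43.3	no
replication	PCOS	rs9312937	5	16836005	MYO10	T	C	0.554	-0.148	0.026	1.8e-08	31.8	no
replication	PCOS	rs3945628	9	126535553	DENND1A	T	C	0.930	-0.340	0.049	2.9e-12	48.7	no
replication	PCOS	rs11031002	11	30215261	FSHB	A	T	0.122	0.217	0.038	9.3e-09	32.9	no
replication	PCOS	rs16727161	11	113952497	ZBTB16	A	G	0.855	0.206	0.036	9.8e-09	32.8	no
replication	PCOS	rs17880096	22	29105202	CHEK2	C	G	0.037	0.335	0.047	1.5e-12	50.0	no
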