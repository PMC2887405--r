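locus_id	class	target_family	n_indica	d_indica	d_sig_indica	hka_p_indica	n_japonica	d_japonica	d_sig_japonica	hka_p_japonica	n_wild	d_wild	d_sig_wild	hka_p_wild	status_reported
MIR164e	MIRNA	NAC	21	-1.90	TRUE	0.101	21	1.18	FALSE	0.285	10	-1.04	FALSE	0.447	Putative
MIR390	MIRNA	TAS3	25	-1.21	FALSE	0.106	20	-0.09	FALSE	0.014	11	-1.23	FALSE	0.257	Putative
MIR395a-b	MIRNA	APS/AST	27	-1.56	FALSE	NA	21	-1.94	TRUE	NA	11	-1.49	FALSE	NA	Putative
TAS3a2	TAS3	ARF	28	-1.86	TRUE	0.029	24	-0.85	FALSE	0.158	10	-1.35	FALSE	0.503	Putative
AK120922	long_hairpin	Unknown	25	0.26	FALSE	0.003	18	-1.77	FALSE	0.055	11	-2.05	TRUE	0.250	ND
MIR164a	MIRNA	Unknown	25	1.54	FALSE	0.129	22	-1.31	FALSE	0.215	11	-0.84	FALSE	0.433	ND
MIR164c	MIRNA	NAC	23	-0.51	FALSE	0.167	23	-0.63	FALSE	0.297	8	0.47	FALSE	0.294	ND
MIR164d	MIRNA	NAC	25	-0.48	FALSE	0.147	21	-1.29	FALSE	0.260	12	-1.54	FALSE	0.464	ND
MIR166f	MIRNA	HD-ZIP	29	-1.02	FALSE	0.161	23	-0.81	FALSE	0.342	10	-0.20	FALSE	0.419	ND
MIR395i-k	MIRNA	APS/AST	25	0.98	FALSE	0.106	18	-0.52	FALSE	0.248	9	-0.60	FALSE	0.245	ND
MIR396f	MIRNA	GRL	21	-0.54	FALSE	0.089	20	0.76	FALSE	0.288	10	-0.68	FALSE	0.470	ND
MIR399a	MIRNA	PT	27	0.35	FALSE	0.099	24	-0.68	FALSE	0.278	14	1.21	FALSE	0.403	ND
MIR399d	MIRNA	PT	23	-2.37	TRUE	0.107	22	-0.87	FALSE	0.002	12	-2.04	TRUE	0.255	ND
MIR399i	MIRNA	PT	22	-0.95	FALSE	0.102	22	-1.08	FALSE	0.196	11	-1.03	FALSE	0.442	ND
MIR440	MIRNA	Unknown	25	0.04	FALSE	0.097	20	-0.57	FALSE	0.137	14	-1.58	FALSE	0.339	ND
MIR443	MIRNA	Unknown	29	0.15	FALSE	0.148	21	-1.57	FALSE	0.274	9	-0.39	FALSE	0.301	ND
MIR1318	MIRNA	Unknown	22	0.34	FALSE	0.078	21	-0.65	FALSE	0.227	12	-0.45	FALSE	0.439	ND
MIR1432	MIRNA	EF	26	0.20	FALSE	0.081	22	-1.30	FALSE	0.176	10	0.57	FALSE	0.382	ND
MIR1862d	MIRNA	NAC	21	0.71	FALSE	0.113	20	-0.14	FALSE	0.270	9	-1.88	TRUE	0.394	ND
MIR1867	MIRNA	Unknown	24	-1.21	FALSE	0.094	24	-1.11	FALSE	0.280	10	-0.94	FALSE	0.493	ND
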