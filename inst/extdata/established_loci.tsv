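cohort	chrom	id	pos	gene	effect_allele	quality_r2	genotyped	maf_low	n_low	or_low	l95_low	u95_low	p_low	maf_all	n_all	or_all	l95_all	u95_all	p_all
first	1	rs2476601	113834946	PTPN22	A	0.99897	Genotyped	0.08676	6118	1.87	1.594	2.194	1.55e-14	0.1112	9450	2.244	2.048	2.458	1.92e-67
first	6	rs9273368	32658698	HLA-DQB1	A	0.97908	Imputed	0.2586	6118	4.073	3.616	4.587	1.24e-118	0.3841	9450	6.018	5.572	6.5	1e-350
first	11	rs689	2160994	INS	A	0.89726	Imputed	0.2572	6118	0.391	0.3354	0.4559	4.02e-33	0.2331	9450	0.4442	0.4098	0.4815	1.03e-86
switched	1	rs2476601	113834946	PTPN22	A	0.99897	Genotyped	0.09515	6460	2.216	1.921	2.557	1.03e-27	0.1152	9465	2.268	2.07	2.484	3.53e-69
switched	6	rs9273368	32658698	HLA-DQB1	A	0.97908	Imputed	0.2584	6460	3.809	3.416	4.247	6.19e-128	0.376	9465	5.937	5.503	6.404	1e-350
switched	11	rs689	2160994	INS	A	0.89726	Imputed	0.259	6460	0.4553	0.3972	0.5218	1.23e-29	0.2366	9465	0.4883	0.4517	0.5279	1.54e-72
switched	12	rs1701704	56034024	IKZF4	T	0.98704	Imputed	0.3276	6460	1.353	1.22	1.501	1.03e-08	0.3427	9465	1.366	1.282	1.455	3.59e-22
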