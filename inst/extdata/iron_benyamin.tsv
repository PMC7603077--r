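snp	effect_allele	baseline_allele	chrom	eaf	beta	se	pvalue	r2	n
rs1800562	A	G	6	0.067	0.328	0.016	2.72e-97	0.013	48972
rs1799945	G	C	6	0.15	0.189	0.010	1.10e-81	0.009	48972
rs855791	G	A	22	0.554	0.181	0.007	1.32e-139	0.016	48972
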