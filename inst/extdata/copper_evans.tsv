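snp	effect_allele	baseline_allele	chrom	eaf	beta	se	pvalue	r2	n
rs1175550	G	A	1	0.23	0.198	0.032	5.03e-10	0.0145	2603
rs2769264	G	T	1	0.18	0.313	0.034	2.63e-20	0.0315	2603
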