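snp	trait	pvalue
rs1800562	LDL cholesterol	1.0e-30
rs1800562	Transferrin saturation	4.1e-180
rs855791	Hemoglobin concentration	2.3e-45
rs1175550	Mean corpuscular hemoglobin	8.0e-12
rs2769264	Selenium levels	6.0e-8
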