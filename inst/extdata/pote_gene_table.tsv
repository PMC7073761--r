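symbol	ensembl_id	localization	gene_size_bp	transcript_variants
POTEA	ENSG00000188877	8p11.1	71036	2
POTEB	ENSG00000233917	15q11.2	31375	4
POTEB2	ENSG00000230031	15q11.2	30943	2
POTEB3	ENSG00000278522	15q11.2	32209	3
POTEC	ENSG00000183206	18p11.21	36247	4
POTED	ENSG00000166351	21q11.2	31728	2
POTEE	ENSG00000188219	2q21.1	47212	5
POTEF	ENSG00000196604	2q21.1	55688	2
POTEG	ENSG00000187537	14q11.2	31856	3
POTEH	ENSG00000198062	22q11.1	31606	3
POTEI	ENSG00000196834	2q21.1	50253	3
POTEJ	ENSG00000222038	2q21.1	46611	1
POTEKP	ENSG00000204434	2q21.1	36396	NA
POTEM	ENSG00000222036	14q11.2	36319	3
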