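gene_id	symbol	group_reported	exons	lir_reported	actin_retrogene	cysteine_repeats	ankyrin_repeats	coiled_coils
ENSG00000188877	POTEA	I	14	half	no	1	7	4
ENSG00000233917	POTEB	II	11	half	no	2	7	1
ENSG00000230031	POTEB2	II	11	half	no	2	7	1
ENSG00000278522	POTEB3	II	11	half	no	3	7	1
ENSG00000183206	POTEC	II	11	half	no	3	7	1
ENSG00000166351	POTED	II	11	half	no	3	7	2
ENSG00000188219	POTEE	III	15	full	yes	3	7	1
ENSG00000196604	POTEF	III	17	full	yes	3	7	1
ENSG00000196834	POTEI	III	15	full	yes	3	7	1
ENSG00000222038	POTEJ	III	15	full	yes	2	7	1
ENSG00000204434	POTEKP	ambiguous	11	full	yes_out_of_cds	NA	NA	NA
ENSG00000187537	POTEG	IV	12	full	yes_out_of_cds	3	7	0
ENSG00000198062	POTEH	IV	12	full	yes_out_of_cds	3	7	0
ENSG00000222036	POTEM	IV	12	full	yes_out_of_cds	3	7	0
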