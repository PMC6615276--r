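miR_Family	MiRBase_ID	Gene_Symbol	Species_ID
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	NOTCH1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	PSEN1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	MAPK1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	PTEN	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	DLL1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	JAG1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	HES1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	RBPJ	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	ADAM17	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	MAML1	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	DTX4	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	NCOR2	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	KAT2B	9606
miR-25-3p/32-5p/92-3p/363-3p/367-3p	hsa-miR-92a-3p	NOTCH2	9606
miR-101-3p	hsa-miR-101-3p	NOTCH1	9606
miR-101-3p	hsa-miR-101-3p	PSEN1	9606
miR-101-3p	hsa-miR-101-3p	JAG1	9606
miR-101-3p	hsa-miR-101-3p	DLL3	9606
miR-101-3p	hsa-miR-101-3p	HES1	9606
miR-101-3p	hsa-miR-101-3p	HEY1	9606
miR-101-3p	hsa-miR-101-3p	ADAM10	9606
miR-101-3p	hsa-miR-101-3p	NUMB	9606
miR-101-3p	hsa-miR-101-3p	LFNG	9606
miR-101-3p	hsa-miR-101-3p	CREBBP	9606
miR-101-3p	hsa-miR-101-3p	EP300	9606
miR-101-3p	hsa-miR-101-3p	STAT3	9606
miR-101-3p	hsa-miR-101-3p	MYC	9606
miR-222-3p	hsa-miR-222-3p	PSEN1	9606
miR-222-3p	hsa-miR-222-3p	CDKN1B	9606
miR-222-3p	hsa-miR-222-3p	TGFBR2	9606
miR-222-3p	hsa-miR-222-3p	KIT	9606
miR-29b-3p	hsa-miR-29b-3p	KLF4	9606
miR-29b-3p	hsa-miR-29b-3p	APC	9606
miR-29b-3p	hsa-miR-29b-3p	STAT3	9606
miR-29b-3p	hsa-miR-29b-3p	GSK3B	9606
miR-29b-3p	hsa-miR-29b-3p	TET1	9606
miR-29b-3p	hsa-miR-29b-3p	DNMT3A	9606
miR-29b-3p	hsa-miR-29b-3p	DNMT3A	9606
miR-302-3p/372-3p/373-3p/520-3p	hsa-miR-302c-3p	NOTCH1	9606
miR-302-3p/372-3p/373-3p/520-3p	hsa-miR-302c-3p	LEFTY1	9606
miR-302-3p/372-3p/373-3p/520-3p	hsa-miR-302c-3p	TGFBR2	9606
miR-302-3p/372-3p/373-3p/520-3p	hsa-miR-302c-3p	CDKN1A	9606
miR-302-3p/372-3p/373-3p/520-3p	mmu-miR-302c-3p	Lefty1	10090
miR-29b-3p	mmu-miR-29b-3p	Dnmt3a	10090
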