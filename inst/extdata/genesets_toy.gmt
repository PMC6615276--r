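NOTCH_SIGNALING	toy	NOTCH1	PSEN1	JAG1	DLL1	DLL3	HES1	HEY1	RBPJ	MAML1	ADAM10	ADAM17	NUMB	LFNG	DTX4
WNT_SIGNALING	toy	APC	GSK3B	MYC	TCF3	CTNNB1	LRP6	AXIN1
DNA_METHYLATION	toy	DNMT3A	DNMT3B	TET1	TET2	UHRF1
JAK_STAT	toy	STAT3	JAK1	JAK2	IL6ST	SOCS3
PLURIPOTENCY_CORE	toy	POU5F1	SOX2	NANOG	KLF4	LIN28A	MYC
TGFB_SIGNALING	toy	TGFBR2	SMAD2	SMAD3	SMAD4	LEFTY1	TGFB3
CELL_CYCLE_G2M	toy	CCNB1	CDK1	PLK1	CDC25C	CDKN1A	CDKN1B
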