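hu_scrnaseq_E	synthetic toy list	KRT15	KRT14	COL17A1	DST	CXCL14
hu_scrnaseq_F	synthetic toy list	KRT15	ITGB1	FAT1	CAV1
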