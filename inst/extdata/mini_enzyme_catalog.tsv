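enzyme_name	motif	cut_offset	cpg_sensitive	chg_sensitive	chh_sensitive	family_id
MspI	CCGG	1	no	no	no	fam_CCGG
HpaII	CCGG	1	yes	no	no	fam_CCGG
TaqAI	TCGA	1	no	no	no	fam_TCGA
XmaI	CCCGGG	1	no	no	no	fam_CCCGGG
BsaWI	WCCGGW	1	no	no	no	fam_WCCGGW
AflIII	ACRYGT	1	no	yes	yes	fam_ACRYGT
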