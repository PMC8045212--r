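chr1	65935074	65959904	LEPR
chr3	57199593	57590187	APPL1
chr7	54813379	55274871	EGFR
chr12	57897794	57918452	DDIT3
chr14	74001650	74022324	ACOT1
chr17	38688566	38738474	CCR7
chr19	56370485	56416408	NLRP4
chr20	33470662	33495348	ACSS2
chr22	24347958	24390254	GSTT1
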