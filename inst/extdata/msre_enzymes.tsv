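name	pattern
AciI	CCGC
HhaI	GCGC
HpyCH4IV	ACGT
HpaII	CCGG
AatII	GACGTC
BstUI	CGCG
ClaI	ATCGAT
EagI	CGGCCG
AgeI	ACCGGT
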