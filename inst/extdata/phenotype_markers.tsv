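PROTEIN	PHENOTYPE	ASSOCIATION_SIGN
MCL1	pro_survival	1
BCL2	pro_survival	1
BCL2L1	pro_survival	1
BAD	pro_apoptotic	1
BCL2L11	pro_apoptotic	1
BAX	pro_apoptotic	1
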