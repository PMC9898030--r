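PROTEIN	ROLE
FLT3	other
PIK3CA	other
AKT1	kinase
MAPK1	kinase
WEE1	kinase
CDK1	kinase
CDC25B	phosphatase
STAT5A	TF
MYC	TF
CDKN1B	other
BAD	other
MCL1	other
BCL2	other
BCL2L11	other
BAX	other
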