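PROTEIN	RESIDUE	EFFECT	PROVENANCE
STAT5A	Y694	activating	curated
AKT1	T308	activating	curated
MAPK1	T185	activating	curated
MYC	S62	activating	curated
CDK1	Y15	inhibiting	curated
CDK1	T161	activating	curated
BAD	S99	inhibiting	curated
WEE1	S139	inhibiting	curated
CDKN1B	T157	inhibiting	curated
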