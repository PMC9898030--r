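ENTITYA	ENTITYB	EFFECT	MECHANISM	RESIDUE	PROVENANCE
FLT3	STAT5A	up-regulates	phosphorylation	Y694	curated
FLT3	PIK3CA	up-regulates	binding		curated
PIK3CA	AKT1	up-regulates	phosphorylation	T308	curated
AKT1	BAD	down-regulates	phosphorylation	S99	curated
AKT1	CDKN1B	down-regulates	phosphorylation	T157	curated
FLT3	MAPK1	up-regulates	phosphorylation	T185	curated
MAPK1	MYC	up-regulates	phosphorylation	S62	curated
WEE1	CDK1	down-regulates	phosphorylation	Y15	curated
CDC25B	CDK1	up-regulates	dephosphorylation	Y15	curated
CDKN1B	CDK1	down-regulates	binding		curated
CDK1	MCL1	down-regulates	phosphorylation	S64	curated
CDK1	BCL2	down-regulates	phosphorylation	S70	curated
CDK1	BAD	up-regulates	phosphorylation	S128	curated
CDK1	BCL2L11	up-regulates	phosphorylation	T112	curated
BCL2	BAX	down-regulates	binding		curated
STAT5A	PIM1	up-regulates	transcriptional		curated
STAT5A	CISH	up-regulates	transcriptional		curated
STAT5A	BCL2L1	up-regulates	transcriptional		curated
MYC	CCND1	up-regulates	transcriptional		curated
MYC	NPM1	up-regulates	transcriptional		curated
MYC	CDKN2A	down-regulates	transcriptional		curated
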