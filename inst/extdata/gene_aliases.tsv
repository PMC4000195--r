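# Editable alias table mapping common/protein names to official gene symbols.
# Entries marked (typo-variant) resolve presumed typographical variants of
# marker names seen in curation sources; review before use on real data.
alias	symbol
COX2	PTGS2
COX-2	PTGS2
UPA	PLAU
VEGF	VEGFA
MMR	MRC1
CD206	MRC1
YM1	CHI3L3
CHI3I3	CHI3L3
FIZZ1	RETNLA
RENTLA	RETNLA
MGL	CLEC10A
ARGINASE	ARG1
ARG	ARG1
IL1	IL1B
TNFA	TNF
INOS	NOS2
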