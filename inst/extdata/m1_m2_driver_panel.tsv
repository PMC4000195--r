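symbol	polarization	evidence	weight
arginase	M2	literature,rtpcr	1
CLEC10A	M2	literature,rtpcr	1
CD206	M2	literature,rtpcr	1
VEGF	M2	literature,rtpcr	1
IL1	M1	literature,rtpcr	1
IL6	M1	literature,rtpcr	1
TNF	M1	literature,rtpcr	1
YM1	M2	literature,rtpcr	1
FIZZ1	M2	literature,rtpcr	1
COX2	M2	literature,rtpcr	1
uPA	M2	literature,rtpcr	1
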