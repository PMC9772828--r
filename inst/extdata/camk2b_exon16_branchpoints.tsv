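species	agez	distance	nonamer	svb_score
mouse	44	26	ccctaacaa	1.77
frog_bp1	18	20	aactaagtc	1.11
frog_bp2	18	24	ctttaacta	0.74
rhesus_macaque	24	26	gcctaaggg	0.83
human	22	26	acctaagag	0.63
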