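isoform	substrate	vmax	vmax_se	h	h_se	ec50	ec50_se
FL	syntide2	1.11	0.02	1.22	0.11	10.30	0.82
d13	syntide2	0.99	0.02	1.20	0.09	7.80	0.56
d16_17	syntide2	1.27	0.03	1.29	0.11	13.65	0.97
d13_16	syntide2	1.35	0.03	1.11	0.11	11.98	1.16
FL	tau441	1.04	0.02	1.53	0.19	12.2	0.90
d16_17	tau441	1.25	0.03	1.58	0.17	18.8	1.30
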