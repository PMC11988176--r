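trait	n	mean	sd	cv_printed	h2	h2_se
BL	1494	123.70	7.14	5.77	0.52	0.02
BH	1494	64.60	3.64	5.63	0.49	0.02
CC	1494	112.24	8.16	7.27	0.48	0.02
WC	1494	110.45	8.79	7.96	0.49	0.02
AC	1494	121.34	8.59	7.08	0.48	0.02
BF	650	11.40	3.08	27.07	0.39	0.02
LMA	650	40.36	7.29	18.05	0.42	0.02
LMD	650	53.18	6.69	12.56	0.45	0.02
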