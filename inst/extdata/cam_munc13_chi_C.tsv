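metal	ax	rh	xy	xz	yz
Dy	-0.14	-1.74	-1.95	3.16	-0.49
Er	0.15	1.46	0.05	-1.00	0.55
Ho	-0.07	-1.42	-0.69	1.46	-0.86
Tb	0.24	-2.80	-0.09	2.91	-2.13
Tm	0.73	3.27	-0.21	-1.29	1.69
Yb	0.09	0.60	0.27	-0.47	0.20
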