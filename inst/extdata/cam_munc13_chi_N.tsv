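metal	ax	rh	xy	xz	yz
Dy	14.90	-24.54	10.43	10.08	-5.66
Er	-4.87	-0.27	-4.76	-5.81	1.64
Ho	6.83	-4.43	3.80	4.71	-4.55
Tb	17.58	2.02	6.83	12.79	-7.43
Tm	-8.86	-6.17	-8.03	-8.68	6.89
Yb	-2.04	2.94	-2.96	-2.86	1.91
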