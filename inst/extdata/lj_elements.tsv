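class	r_min_half	epsilon
C	1.9080	0.0860
N	1.8240	0.1700
O	1.6612	0.2100
S	2.0000	0.2500
H	1.3870	0.0157
P	2.1000	0.2000
X	1.9480	0.2650
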