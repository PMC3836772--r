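scale	aa	value
kyte_doolittle_1982	A	1.8
kyte_doolittle_1982	R	-4.5
kyte_doolittle_1982	N	-3.5
kyte_doolittle_1982	D	-3.5
kyte_doolittle_1982	C	2.5
kyte_doolittle_1982	Q	-3.5
kyte_doolittle_1982	E	-3.5
kyte_doolittle_1982	G	-0.4
kyte_doolittle_1982	H	-3.2
kyte_doolittle_1982	I	4.5
kyte_doolittle_1982	L	3.8
kyte_doolittle_1982	K	-3.9
kyte_doolittle_1982	M	1.9
kyte_doolittle_1982	F	2.8
kyte_doolittle_1982	P	-1.6
kyte_doolittle_1982	S	-0.8
kyte_doolittle_1982	T	-0.7
kyte_doolittle_1982	W	-0.9
kyte_doolittle_1982	Y	-1.3
kyte_doolittle_1982	V	4.2
fauchere_pliska_1983	A	0.31
fauchere_pliska_1983	R	-1.01
fauchere_pliska_1983	N	-0.60
fauchere_pliska_1983	D	-0.77
fauchere_pliska_1983	C	1.54
fauchere_pliska_1983	Q	-0.22
fauchere_pliska_1983	E	-0.64
fauchere_pliska_1983	G	0.00
fauchere_pliska_1983	H	0.13
fauchere_pliska_1983	I	1.80
fauchere_pliska_1983	L	1.70
fauchere_pliska_1983	K	-0.99
fauchere_pliska_1983	M	1.23
fauchere_pliska_1983	F	1.79
fauchere_pliska_1983	P	0.72
fauchere_pliska_1983	S	-0.04
fauchere_pliska_1983	T	0.26
fauchere_pliska_1983	W	2.25
fauchere_pliska_1983	Y	0.96
fauchere_pliska_1983	V	1.22
wolfenden_1981	A	1.94
wolfenden_1981	R	-19.92
wolfenden_1981	N	-9.68
wolfenden_1981	D	-10.95
wolfenden_1981	C	-1.24
wolfenden_1981	Q	-9.38
wolfenden_1981	E	-10.20
wolfenden_1981	G	2.39
wolfenden_1981	H	-10.27
wolfenden_1981	I	2.15
wolfenden_1981	L	2.28
wolfenden_1981	K	-9.52
wolfenden_1981	M	-1.48
wolfenden_1981	F	-0.76
wolfenden_1981	S	-5.06
wolfenden_1981	T	-4.88
wolfenden_1981	W	-5.88
wolfenden_1981	Y	-6.11
wolfenden_1981	V	1.99
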