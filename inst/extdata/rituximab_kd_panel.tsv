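variant	receptor	value
WT	FcgRI	8.67E-09
WT	FcgRIIb	2.41E-06
WT	FcgRIIIa-F158	9.44E-07
WT	FcgRIIIa-V158	4.03E-07
WT	FcgRIIa-H131	1.09E-06
WT	FcgRIIa-R131	1.25E-06
WT	FcRn-pH6	2.10E-08
WT	FcRn-pH7.4	NB
H268E/K326M/I332E	FcgRI	5.15E-09
H268E/K326M/I332E	FcgRIIb	1.05E-06
H268E/K326M/I332E	FcgRIIIa-F158	1.58E-07
H268E/K326M/I332E	FcgRIIIa-V158	6.91E-08
H268E/K326M/I332E	FcgRIIa-H131	8.82E-07
H268E/K326M/I332E	FcgRIIa-R131	7.38E-07
H268E/K326M/I332E	FcRn-pH6	2.60E-08
H268E/K326M/I332E	FcRn-pH7.4	NB
H268E/K326S/I332E	FcgRI	5.18E-09
H268E/K326S/I332E	FcgRIIb	1.13E-06
H268E/K326S/I332E	FcgRIIIa-F158	1.51E-07
H268E/K326S/I332E	FcgRIIIa-V158	7.47E-08
H268E/K326S/I332E	FcgRIIa-H131	8.14E-07
H268E/K326S/I332E	FcgRIIa-R131	8.03E-07
H268E/K326S/I332E	FcRn-pH6	2.50E-08
H268E/K326S/I332E	FcRn-pH7.4	NB
H268E/K326I/I332E	FcgRI	6.11E-09
H268E/K326I/I332E	FcgRIIb	1.69E-06
H268E/K326I/I332E	FcgRIIIa-F158	3.11E-07
H268E/K326I/I332E	FcgRIIIa-V158	1.43E-07
H268E/K326I/I332E	FcgRIIa-H131	1.95E-06
H268E/K326I/I332E	FcgRIIa-R131	1.21E-06
H268E/K326I/I332E	FcRn-pH6	2.57E-08
H268E/K326I/I332E	FcRn-pH7.4	NB
H268E/A330Y/I332D	FcgRI	5.04E-09
H268E/A330Y/I332D	FcgRIIb	1.47E-06
H268E/A330Y/I332D	FcgRIIIa-F158	9.40E-08
H268E/A330Y/I332D	FcgRIIIa-V158	6.06E-08
H268E/A330Y/I332D	FcgRIIa-H131	5.26E-07
H268E/A330Y/I332D	FcgRIIa-R131	6.8E-07
H268E/A330Y/I332D	FcRn-pH6	2.19E-08
H268E/A330Y/I332D	FcRn-pH7.4	NB
H268E/A330T/I332E	FcgRI	5.64E-09
H268E/A330T/I332E	FcgRIIb	9.06E-07
H268E/A330T/I332E	FcgRIIIa-F158	1.56E-07
H268E/A330T/I332E	FcgRIIIa-V158	6.11E-08
H268E/A330T/I332E	FcgRIIa-H131	6.27E-07
H268E/A330T/I332E	FcgRIIa-R131	5.75E-07
H268E/A330T/I332E	FcRn-pH6	2.15E-08
H268E/A330T/I332E	FcRn-pH7.4	NB
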