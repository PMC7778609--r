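variant	receptor	value
WT	FcgRI	1.04E-08
WT	FcgRIIb	6.26E-06
WT	FcgRIIIa-F158	2.12E-06
WT	FcgRIIIa-V158	5.95E-07
WT	FcgRIIa-H131	1.39E-06
WT	FcgRIIa-R131	2.29E-06
WT	FcRn-pH6	3.77E-08
WT	FcRn-pH7.4	NB
V266I/S267E/K326V/L328A	FcgRI	9.43E-09
V266I/S267E/K326V/L328A	FcgRIIb	3.69E-08
V266I/S267E/K326V/L328A	FcgRIIIa-F158	8.16E-07
V266I/S267E/K326V/L328A	FcgRIIIa-V158	4.14E-07
V266I/S267E/K326V/L328A	FcgRIIa-H131	7.65E-07
V266I/S267E/K326V/L328A	FcgRIIa-R131	2.11E-08
V266I/S267E/K326V/L328A	FcRn-pH6	5.32E-08
V266I/S267E/K326V/L328A	FcRn-pH7.4	NB
G236D/V266I/S267E/K326V/L328A	FcgRI	1.84E-08
G236D/V266I/S267E/K326V/L328A	FcgRIIb	1.82E-08
G236D/V266I/S267E/K326V/L328A	FcgRIIIa-F158	4.66E-06
G236D/V266I/S267E/K326V/L328A	FcgRIIIa-V158	4.98E-06
G236D/V266I/S267E/K326V/L328A	FcgRIIa-H131	1.40E-06
G236D/V266I/S267E/K326V/L328A	FcgRIIa-R131	1.94E-08
G236D/V266I/S267E/K326V/L328A	FcRn-pH6	5.40E-08
G236D/V266I/S267E/K326V/L328A	FcRn-pH7.4	NB
P238D/V266I/S267E/K326V/L328A	FcgRI	1.78E-08
P238D/V266I/S267E/K326V/L328A	FcgRIIb	1.08E-06
P238D/V266I/S267E/K326V/L328A	FcgRIIIa-F158	WB
P238D/V266I/S267E/K326V/L328A	FcgRIIIa-V158	NB
P238D/V266I/S267E/K326V/L328A	FcgRIIa-H131	NB
P238D/V266I/S267E/K326V/L328A	FcgRIIa-R131	1.98E-06
P238D/V266I/S267E/K326V/L328A	FcRn-pH6	5.86E-08
P238D/V266I/S267E/K326V/L328A	FcRn-pH7.4	NB
S267E/L328F	FcgRI	8.78E-09
S267E/L328F	FcgRIIb	2.39E-08
S267E/L328F	FcgRIIIa-F158	4.24E-06
S267E/L328F	FcgRIIIa-V158	5.22E-06
S267E/L328F	FcgRIIa-H131	1.45E-06
S267E/L328F	FcgRIIa-R131	1.30E-08
S267E/L328F	FcRn-pH6	3.91E-08
S267E/L328F	FcRn-pH7.4	NB
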