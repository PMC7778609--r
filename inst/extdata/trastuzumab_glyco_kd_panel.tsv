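variant	receptor	value
H268E/K326S/I332E(defucosylation)	FcgRIIb	1.46E-06
H268E/K326S/I332E(defucosylation)	FcgRIIIa-F158	2.62E-09
H268E/K326S/I332E(defucosylation)	FcgRIIIa-V158	1.36E-09
H268E/K326S/I332E(defucosylation)	FcgRIIa-H131	6.69E-07
H268E/K326S/I332E(defucosylation)	FcgRIIa-R131	3.69E-07
H268E/K326M/I332E(defucosylation)	FcgRIIb	1.03E-06
H268E/K326M/I332E(defucosylation)	FcgRIIIa-F158	3.55E-09
H268E/K326M/I332E(defucosylation)	FcgRIIIa-V158	1.71E-09
H268E/K326M/I332E(defucosylation)	FcgRIIa-H131	1.04E-06
H268E/K326M/I332E(defucosylation)	FcgRIIa-R131	4.20E-07
WT (defucosylation)	FcgRIIb	1.78E-06
WT (defucosylation)	FcgRIIIa-F158	4.65E-08
WT (defucosylation)	FcgRIIIa-V158	1.23E-08
WT (defucosylation)	FcgRIIa-H131	2.09E-06
WT (defucosylation)	FcgRIIa-R131	1.46E-06
WT (fucosylation)	FcgRIIb	1.24E-06
WT (fucosylation)	FcgRIIIa-F158	1.74E-07
WT (fucosylation)	FcgRIIIa-V158	3.85E-08
WT (fucosylation)	FcgRIIa-H131	1.00E-06
WT (fucosylation)	FcgRIIa-R131	1.50E-06
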