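sample_id	group	av_score	lactobacillary_grade
AV01	AV	1	III
AV02	AV	6	IIa
AV03	AV	7	III
AV04	AV	7	IIb
AV05	AV	5	IIb
AV06	AV	6	IIb
BV01	BV	NA	IIb
BV02	BV	NA	III
BV03	BV	NA	IIb
BV04	BV	NA	III
BV05	BV	NA	III
BV06	BV	NA	III
NL01	NL	NA	I
NL02	NL	NA	I
NL03	NL	NA	I
NL04	NL	NA	I
NL05	NL	NA	I
NL06	NL	NA	I
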