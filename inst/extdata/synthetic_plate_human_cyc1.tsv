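assay	well_type	sample_id	concentration	ct	dilution_factor
human_cyc1	standard		100	31.3326736367062	1
human_cyc1	standard		100	31.2818696273933	1
human_cyc1	standard		1000	27.9542988007556	1
human_cyc1	standard		1000	28.0028660857834	1
human_cyc1	standard		10000	24.9434619209045	1
human_cyc1	standard		10000	24.5334588607463	1
human_cyc1	standard		1e+05	21.1714299139922	1
human_cyc1	standard		1e+05	21.2867257438377	1
human_cyc1	standard		1e+06	17.9872852222911	1
human_cyc1	standard		1e+06	17.7749731306643	1
human_cyc1	standard		1e+07	14.5695922261816	1
human_cyc1	standard		1e+07	14.526582809159	1
human_cyc1	standard		1e+08	11.251329842768	1
human_cyc1	standard		1e+08	11.2869810327684	1
human_cyc1	sample	AV01		18.7829890251868	20
human_cyc1	sample	AV01		18.7622687124764	20
human_cyc1	sample	AV02		20.1651953669917	20
human_cyc1	sample	AV02		20.1408690402396	20
human_cyc1	sample	AV03		18.5660158074243	20
human_cyc1	sample	AV03		18.4598082163538	20
human_cyc1	sample	AV04		22.0644649989656	20
human_cyc1	sample	AV04		21.6549687421433	20
human_cyc1	sample	AV05		22.3771384555175	20
human_cyc1	sample	AV05		22.339334814385	20
human_cyc1	sample	AV06		20.6381395763308	20
human_cyc1	sample	AV06		20.7252301732334	20
human_cyc1	sample	BV01		21.0744911994836	20
human_cyc1	sample	BV01		21.1559821360335	20
human_cyc1	sample	BV02		24.1246253309139	20
human_cyc1	sample	BV02		24.5276920845071	20
human_cyc1	sample	BV03		20.9731705883939	20
human_cyc1	sample	BV03		21.0536820700211	20
human_cyc1	sample	BV04		21.4892105582154	20
human_cyc1	sample	BV04		21.2115019812496	20
human_cyc1	sample	BV05		21.0783061942075	20
human_cyc1	sample	BV05		20.9035365379163	20
human_cyc1	sample	BV06		19.7716169715649	20
human_cyc1	sample	BV06		19.6764038337251	20
human_cyc1	sample	NL01		25.7973748478431	20
human_cyc1	sample	NL01		25.792921883997	20
human_cyc1	sample	NL02		21.0206024510783	20
human_cyc1	sample	NL02		20.9906151379037	20
human_cyc1	sample	NL03		20.9118626906891	20
human_cyc1	sample	NL03		20.9659538795289	20
human_cyc1	sample	NL04		22.2307584088472	20
human_cyc1	sample	NL04		22.3750464479886	20
human_cyc1	sample	NL05		24.4226465251287	20
human_cyc1	sample	NL05		24.6329226407663	20
human_cyc1	sample	NL06		23.7069069641073	20
human_cyc1	sample	NL06		23.8701722494035	20
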