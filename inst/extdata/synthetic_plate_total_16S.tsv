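assay	well_type	sample_id	concentration	ct	dilution_factor
total_16S	standard		100	31.2379931167136	1
total_16S	standard		100	31.2583892819786	1
total_16S	standard		1000	27.9233227430373	1
total_16S	standard		1000	28.22426760961	1
total_16S	standard		10000	24.3678901949738	1
total_16S	standard		10000	24.588327824758	1
total_16S	standard		1e+05	21.1915980259538	1
total_16S	standard		1e+05	21.3315685289842	1
total_16S	standard		1e+06	18.3802302734377	1
total_16S	standard		1e+06	18.2923219681548	1
total_16S	standard		1e+07	14.5908390073539	1
total_16S	standard		1e+07	14.6001434543326	1
total_16S	standard		1e+08	11.4544087238379	1
total_16S	standard		1e+08	11.409218758406	1
total_16S	sample	AV01		20.2774670063457	20
total_16S	sample	AV01		20.4075459402406	20
total_16S	sample	AV02		18.9919477779796	20
total_16S	sample	AV02		18.9849057413166	20
total_16S	sample	AV03		18.2028444091678	20
total_16S	sample	AV03		17.982168864889	20
total_16S	sample	AV04		17.4236395618366	20
total_16S	sample	AV04		17.8512821111236	20
total_16S	sample	AV05		18.8984435861141	20
total_16S	sample	AV05		18.9449081631925	20
total_16S	sample	AV06		20.4607557258137	20
total_16S	sample	AV06		20.4356491122866	20
total_16S	sample	BV01		12.0319790778044	20
total_16S	sample	BV01		12.2666646767925	20
total_16S	sample	BV02		10.2767459875743	20
total_16S	sample	BV02		10.6733952870074	20
total_16S	sample	BV03		10.2170187386494	20
total_16S	sample	BV03		10.0935817931798	20
total_16S	sample	BV04		8.9292542814443	20
total_16S	sample	BV04		9.2810244943125	20
total_16S	sample	BV05		12.4552764604015	20
total_16S	sample	BV05		12.3910583505336	20
total_16S	sample	BV06		11.5306457230368	20
total_16S	sample	BV06		11.4771832152461	20
total_16S	sample	NL01		13.6246821061954	20
total_16S	sample	NL01		14.0339593838369	20
total_16S	sample	NL02		18.6931665084984	20
total_16S	sample	NL02		19.0307477996751	20
total_16S	sample	NL03		14.4347409777509	20
total_16S	sample	NL03		14.2916869120348	20
total_16S	sample	NL04		16.9719483702481	20
total_16S	sample	NL04		16.8956484475719	20
total_16S	sample	NL05		12.8658869324671	20
total_16S	sample	NL05		12.7307839898622	20
total_16S	sample	NL06		15.7215864000432	20
total_16S	sample	NL06		15.6315291356986	20
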