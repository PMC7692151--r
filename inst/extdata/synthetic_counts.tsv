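sample_id	ASV01	ASV02	ASV03	ASV04	ASV05	ASV06	ASV07	ASV08	ASV09	ASV10	ASV11	ASV12	ASV13	ASV14
AV01	0	0	0	8093	23	0	6312	0	708	21	6337	374	0	202
AV02	47	449	760	0	874	0	16554	1	131	5624	0	450	168	6
AV03	166	0	0	0	2936	1	8	2133	23	11715	0	844	931	3353
AV04	3	0	0	0	14409	1795	295	18	1	19	14	342	0	98
AV05	4055	1337	0	176	28	0	2594	30	0	4	7	1	153	0
AV06	22618	3307	0	2	255	0	2349	1	1516	0	0	0	469	1414
BV01	6094	1361	448	8658	1130	503	1366	36	9782	0	31	0	70	0
BV02	7508	2	4921	1199	1312	94	7287	88	3298	0	2	50	0	7
BV03	1842	164	5310	4647	9238	85	876	1151	722	0	726	453	0	20
BV04	654	0	709	540	1774	9	4531	32	7	65	0	4	0	1
BV05	250	53	354	7710	1223	452	6082	5207	5473	280	53	149	8	0
BV06	510	3	2125	987	2749	1	25	5508	683	0	5	3	0	15
NL01	26626	348	0	0	0	0	0	193	135	0	0	420	0	376
NL02	1531	1298	0	0	0	0	0	4	119	0	0	0	8704	0
NL03	22660	3053	697	0	28	0	0	7	243	0	0	2	41	780
NL04	3692	17811	0	0	0	0	0	2159	0	0	548	0	15	24
NL05	2022	7661	21	169	5	0	479	1090	116	0	9	626	0	0
NL06	15675	6943	1911	176	31	0	0	5	49	0	0	32	0	0
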