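gene_id	a1	a2	a3	a4	a5	a6	b1	b2	b3	b4	b5	b6
gene00001	176	65	143	204	218	173	106	102	117	475	167	248
gene00002	348	324	334	319	151	396	251	307	175	212	361	268
gene00003	146	104	158	182	165	191	89	178	137	62	246	75
gene00004	168	86	176	297	293	336	1302	1060	689	1098	1685	1963
gene00005	117	71	71	130	112	109	25	22	28	23	35	21
gene00006	159	119	207	163	279	50	48	34	33	64	33	34
gene00007	67	56	105	52	42	95	40	58	39	41	71	43
gene00008	259	269	99	385	160	158	633	425	1422	602	833	744
gene00009	87	160	156	72	93	206	60	46	152	147	94	78
gene00010	43	41	48	34	49	41	36	37	42	30	65	17
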