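sample_id	otu1	otu2	otu3	otu4	otu5	otu6	otu7	otu8	otu9	otu10	otu11	otu12	otu13	otu14	otu15
ind1	114	209	79	52	4	18	15	9	0	0	0	0	0	0	0
ind2	130	129	67	119	4	19	0	28	4	0	0	0	0	0	0
ind3	162	171	47	4	23	12	19	35	27	0	0	0	0	0	0
ind4	253	128	46	7	26	23	4	6	1	6	0	0	0	0	0
ind5	155	74	117	14	33	0	6	27	1	70	0	0	3	0	0
ind6	167	181	75	60	5	0	1	7	4	0	0	0	0	0	0
ind7	142	208	97	34	13	5	0	0	1	0	0	0	0	0	0
ind8	222	157	52	7	2	1	22	11	24	0	0	0	2	0	0
ind9	170	141	45	53	15	70	2	4	0	0	0	0	0	0	0
ind10	190	151	53	33	24	1	20	28	0	0	0	0	0	0	0
ind11	168	224	31	60	1	8	5	2	1	0	0	0	0	0	0
ind12	122	259	41	13	10	11	44	0	0	0	0	0	0	0	0
ind13	204	212	33	6	4	29	6	0	5	1	0	0	0	0	0
ind14	218	143	86	15	26	1	3	4	1	0	3	0	0	0	0
ind15	209	145	25	50	4	38	10	0	7	0	0	0	1	11	0
ind16	275	77	112	10	17	9	0	0	0	0	0	0	0	0	0
ind17	139	188	99	29	17	1	6	17	1	3	0	0	0	0	0
ind18	215	127	66	47	11	13	12	4	2	0	2	0	0	1	0
ind19	160	129	115	33	4	1	10	34	2	10	2	0	0	0	0
ind20	138	133	135	37	1	39	0	2	9	5	1	0	0	0	0
ind21	262	157	23	6	32	16	0	1	0	0	0	3	0	0	0
ind22	220	193	50	7	0	3	25	0	0	0	0	1	1	0	0
ind23	311	94	26	51	0	13	2	3	0	0	0	0	0	0	0
ind24	236	74	119	8	13	4	36	0	1	6	3	0	0	0	0
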