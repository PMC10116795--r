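sample_id	pc1	age
ind1	-1.1934	32
ind2	-0.348	68
ind3	0.5328	50
ind4	-0.711	39
ind5	-0.199	39
ind6	-0.2814	66
ind7	1.1709	32
ind8	2.2887	66
ind9	-1.0689	52
ind10	1.9062	48
ind11	2.1318	32
ind12	0.2315	40
ind13	0.8969	25
ind14	-1.7388	29
ind15	0.4688	66
ind16	-0.5441	67
ind17	-0.1654	45
ind18	0.5522	25
ind19	1.0333	46
ind20	-0.0462	27
ind21	2.6387	59
ind22	0.589	26
ind23	-0.2024	37
ind24	0.4416	36
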