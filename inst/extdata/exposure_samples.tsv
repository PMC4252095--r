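dose	fraction	label	cells	c0	c1	c2	c3	c4	c5	c6	c7	c8	c9	c10	c11	c12	c13	c14	c15
2	1	2Gy-100	498	358	125	15	0	0	0	0	0	0	0	0	0	0	0	0	0
6	0.3	6Gy-30	400	369	2	6	7	7	8	1	0	0	0	0	0	0	0	0	0
6	0.7	6Gy-70	300	201	8	34	28	19	7	1	0	1	0	1	0	0	0	0	0
6	1	6Gy-100	150	1	16	54	42	21	9	4	2	1	0	0	0	0	0	0	0
12	0.3	12Gy-30	250	233	0	0	1	2	2	8	1	1	1	1	0	0	0	0	0
12	0.7	12Gy-70	150	124	0	0	4	4	3	5	3	3	2	2	0	0	0	0	0
12	1	12Gy-100	150	0	1	3	14	22	30	31	22	14	4	6	2	1	0	0	0
17	1	17Gy-100	100	0	0	0	2	2	4	6	10	16	11	21	13	7	4	2	2
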