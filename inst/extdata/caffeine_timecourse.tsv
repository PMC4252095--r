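dose	label	cells	c0	c1	c2	c3	c4	c5	c6	c7	c8	c9	c10	c11	c12	c13	c14	c15
10	48h	150	0	0	0	3	10	20	28	32	17	16	18	3	1	0	1	1
10	51h	150	0	0	0	1	8	23	21	30	22	17	10	10	6	1	1	0
10	54h	150	0	0	0	0	13	21	31	24	25	20	9	7	0	0	0	0
10	57h	150	0	0	0	3	18	40	35	25	16	9	4	0	0	0	0	0
10	60h	150	0	0	3	18	27	16	34	26	11	12	3	0	0	0	0	0
10	72h	150	0	3	17	40	37	23	16	9	2	2	0	0	1	0	0	0
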