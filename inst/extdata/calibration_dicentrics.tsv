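dose	cells	c0	c1	c2	c3	c4	c5	c6	c7	c8	c9	c10	c11	c12	c13	c14	c15	c16	c17	c18
0	2000	1999	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0.1	2000	1989	11	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0.5	2000	1922	78	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
1	1000	886	108	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
3	500	213	192	85	9	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
5	150	3	23	58	38	15	10	2	1	0	0	0	0	0	0	0	0	0	0	0
7	150	0	4	23	35	35	29	10	9	4	1	0	0	0	0	0	0	0	0	0
10	150	0	0	0	3	18	40	35	25	16	9	4	0	0	0	0	0	0	0	0
15	100	0	0	0	0	3	10	12	21	10	16	7	7	7	3	1	3	0	0	0
20	100	0	0	0	0	0	6	9	10	12	17	13	9	6	8	6	1	1	2	0
25	100	0	0	0	0	0	4	5	5	8	18	16	12	7	3	9	4	3	3	3
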