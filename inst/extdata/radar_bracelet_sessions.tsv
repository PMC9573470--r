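session	band	radar	reference	printed_error_pct
1	heart	69	71	2.8
2	heart	69	72	4.2
3	heart	72	75	4.0
4	heart	76	74	2.7
5	heart	85	80	6.3
6	heart	66	70	5.7
7	heart	71	74	4.1
8	heart	80	80	0.0
9	heart	97	101	4.0
10	heart	111	106	4.7
11	heart	70	71	1.4
12	heart	81	85	4.7
13	heart	92	89	3.4
14	heart	105	101	4.0
15	heart	109	112	2.7
1	resp	14	14	0.0
2	resp	16	15	6.7
3	resp	16	17	5.9
4	resp	19	21	9.5
5	resp	19	20	5.0
6	resp	21	23	8.7
7	resp	22	22	0.0
8	resp	24	24	0.0
9	resp	17	18	5.6
10	resp	21	20	5.0
11	resp	22	23	4.3
12	resp	24	23	4.3
13	resp	18	19	5.3
14	resp	27	26	3.8
15	resp	30	29	3.4
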