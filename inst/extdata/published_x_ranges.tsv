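r	n	x_low	x_high
0.25	5	5	5
0.25	10	11	11
0.25	11	12	12
0.25	12	13	13
0.25	13	14	15
0.25	14	15	16
0.25	15	16	17
0.25	16	18	18
0.25	17	19	19
0.25	18	20	21
0.25	30	33	35
0.25	40	44	46
0.25	50	56	58
0.25	60	67	71
0.33	5	6	6
0.33	10	12	12
0.33	11	13	14
0.33	12	14	15
0.33	13	16	16
0.33	14	17	18
0.33	15	18	19
0.33	16	19	20
0.33	17	21	21
0.33	18	22	23
0.33	30	36	38
0.33	40	49	51
0.33	50	61	64
0.33	60	74	80
0.5	5	7	7
0.5	10	14	15
0.5	11	16	17
0.5	12	17	19
0.5	13	19	20
0.5	14	21	22
0.5	15	22	23
0.5	16	24	25
0.5	17	25	26
0.5	18	27	28
0.5	30	44	47
0.5	40	60	62
0.5	50	75	78
0.5	60	91	101
1	5	11	12
1	10	23	25
1	11	25	27
1	12	28	30
1	13	30	32
1	14	33	35
1	15	35	37
1	16	37	39
1	17	40	42
1	18	42	44
1	30	71	75
1	40	95	100
1	50	120	124
1	60	144	166
2	5	18	22
2	10	40	44
2	11	45	48
2	12	49	53
2	13	53	57
2	14	58	61
2	15	62	66
2	16	66	70
2	17	71	74
2	18	75	79
2	30	125	133
2	40	168	176
2	50	212	220
2	60	255	300
4	5	35	42
4	10	75	83
4	11	83	91
4	12	92	99
4	13	100	107
4	14	108	116
4	15	116	124
4	16	124	132
4	17	132	140
4	18	140	148
4	30	234	250
4	40	316	331
4	50	397	413
4	60	478	569
8	5	67	82
8	10	146	161
8	11	162	177
8	12	177	193
8	13	193	208
8	14	209	224
8	15	225	240
8	16	240	256
8	17	256	271
8	18	272	287
8	30	453	484
8	40	611	642
8	50	769	800
8	60	926	1109
16	5	131	162
16	10	287	317
16	11	318	348
16	12	349	379
16	13	380	410
16	14	411	441
16	15	442	472
16	16	473	503
16	17	504	535
16	18	535	566
16	30	892	953
16	40	1202	1264
16	50	1512	1574
16	60	1823	2000
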