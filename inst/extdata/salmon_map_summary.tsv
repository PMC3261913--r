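chromosome	n_snps	female_cM	male_cM	ratio
ssa01	386	135.3	130.1	1.04
ssa02	241	121.8	27	4.51
ssa03	291	115.4	61	1.89
ssa04	224	112.4	99.1	1.13
ssa05	255	116.6	54.9	2.12
ssa06	251	119.9	68.4	1.75
ssa07	158	114	72.2	1.58
ssa08	71	56.2	7.6	7.39
ssa09	311	106.8	79.1	1.35
ssa10	296	88.1	65.8	1.34
ssa11	233	85.1	58.4	1.46
ssa12	242	118.6	66.5	1.78
ssa13	285	89.7	84.1	1.07
ssa14	206	69.2	65.1	1.06
ssa15	215	80.1	82.3	0.97
ssa16	192	63	18.6	3.39
ssa17	166	69.3	11.3	6.13
ssa18	164	73.8	37.7	1.96
ssa19	157	66.3	71.6	0.93
ssa20	177	63.3	49.2	1.29
ssa21	107	53.9	66.7	0.81
ssa22	160	58.8	62.5	0.94
ssa23	126	51.4	58.1	0.88
ssa24	115	58.7	58.6	1.00
ssa25	117	55	56.2	0.98
ssa26	145	81.6	77.5	1.05
ssa27	162	53.6	57.7	0.93
ssa28	96	53.7	44.9	1.20
ssa29	101	71.4	60.7	1.18
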