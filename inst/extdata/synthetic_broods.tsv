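genotype	temperature	eggs_laid	hatched	replicate
wild-type	15	210	208	1
wild-type	15	195	194	1
wild-type	15	223	221	2
wild-type	15	188	187	2
wild-type	15	205	204	3
wild-type	15	217	215	3
wild-type	24	198	196	1
wild-type	24	230	229	1
wild-type	24	207	206	2
wild-type	24	185	183	2
wild-type	24	214	213	3
wild-type	24	226	224	3
ts-mutant	15	162	148	1
ts-mutant	15	175	159	1
ts-mutant	15	158	146	2
ts-mutant	15	181	166	2
ts-mutant	15	169	153	3
ts-mutant	15	173	160	3
ts-mutant	24	142	1	1
ts-mutant	24	156	0	1
ts-mutant	24	138	2	2
ts-mutant	24	149	0	2
ts-mutant	24	161	1	3
ts-mutant	24	144	0	3
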