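orf_id	putative_function	mw_kda	empai
177	Major capsid protein	54	24.470
63	Hypothetical protein	20	21.526
120	Hypothetical protein	42	9.380
432	Hypothetical protein	114	8.871
433	LYR motif-containing protein	114	8.208
255	Histone H3	18	6.906
149	High-mobility-group protein	11	5.268
61	Histone H2B	20	5.232
145	Ser/Thr protein kinase	82	4.125
249	Hypothetical protein	19	3.953
405	Hypothetical protein	19	3.953
72	Hypothetical protein	22	3.809
9	Hypothetical protein	27	3.467
361	Rho termination factor N-terminal domain-containing protein	56	3.354
28	Hypothetical protein	24	3.102
116	Rho termination factor N-terminal domain-containing protein	27	3.048
236	Hypothetical protein	70	2.722
8	Hypothetical protein	19	2.622
5	Rho termination factor N-terminal domain-containing protein	46	2.475
321	Rho termination factor N-terminal domain-containing protein	59	2.307
351	Hypothetical protein	24	2.292
445	Hypothetical protein	76	2.246
232	Hypothetical protein	38	2.240
254	Histone H4	10	2.203
182	Glutaredoxin	19	2.143
179	Hypothetical protein	262	2.107
413	Hypothetical protein	91	1.970
189	Hypothetical protein	14	1.963
74	Hypothetical protein	60	1.913
66	Hypothetical protein	23	1.898
442	Hypothetical protein	23	1.898
226	Putative membrane protein	40	1.807
239	Hypothetical protein	15	1.788
337	FG-GAP repeat-containing protein	74	1.578
339	Hypothetical protein	24	1.505
268	Hypothetical protein	50	1.456
454	PAN domain-containing protein	17	1.430
113	Hypothetical protein	29	1.394
1	Hypothetical protein	14	1.385
238	Hypothetical protein	14	1.369
341	PAN domain-containing protein	14	1.340
333	Hypothetical protein	24	1.182
421	Hypothetical protein	73	1.014
443	Hypothetical protein	24	0.894
262	Hypothetical protein	122	0.877
244	Putative tRNA-His guanylyltransferase	30	0.875
62	Hypothetical protein	25	0.873
180	Hypothetical protein	26	0.830
190	Hypothetical protein	96	0.829
281	Hypothetical protein	37	0.828
331	Hypothetical protein	77	0.787
111	Hypothetical protein	27	0.786
197	Hypothetical protein	45	0.758
458	Hypothetical protein	28	0.744
386	Hypothetical protein	17	0.720
338	Hypothetical protein	23	0.719
447	Hypothetical protein	23	0.719
200	Hypothetical protein	62	0.679
318	Histone H2A	25	0.663
349	Thioredoxin	19	0.620
122	Hypothetical protein	27	0.600
134	Hypothetical protein	14	0.565
241	Hypothetical protein	15	0.516
154	Hypothetical protein	15	0.507
307	Putative proliferating cell nuclear antigen	31	0.503
306	Hypothetical protein	54	0.422
329	Putative myristoylated membrane protein	27	0.418
229	Putative VV A32-like packaging ATPase	37	0.405
123	PKD domain-containing protein	28	0.398
103	Hypothetical protein	29	0.389
93	DUF4804 domain-containing protein	49	0.383
279	Ribonucleotide reductase large subunit	72	0.365
436	Hypothetical protein	23	0.305
332	Hypothetical protein	24	0.299
308	Hypothetical protein	78	0.281
256	Hypothetical protein	41	0.263
434	Hypothetical protein	43	0.248
340	Nucleoside diphosphate kinase	38	0.182
188	Hypothetical protein	105	0.096
310	Hypothetical protein	45	0.073
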