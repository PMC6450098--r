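group	n_species	max	min	mean	median	sd
Pandoraviruses	3	63.66	60.66	62.01	61.72	1.52
Medusavirus	1	61.68	61.68	61.68	61.68	NA
Mollivirus	1	60.11	60.11	60.11	60.11	NA
Iridoviridae	37	55.37	27.23	46.33	53.92	11.04
Ascoviridae	5	49.66	35.23	45.17	45.87	5.85
Kaumoebavirus	1	43.70	43.70	43.70	43.70	NA
Marseilleviridae	12	44.73	42.69	43.49	43.04	0.82
Phycodnaviridae	24	55.00	30.37	43.35	41.92	5.49
Asfarviridae	4	38.95	38.59	38.77	38.76	0.17
Pithoviruses	2	41.49	35.80	38.65	38.65	4.03
Faustoviruses	8	37.76	36.21	36.84	36.48	0.73
Poxviridae	61	66.69	17.78	33.86	32.33	12.71
Pacmanvirus	1	33.62	33.62	33.62	33.62	NA
Mimiviridae	14	31.99	23.34	26.96	26.64	2.47
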