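virus_orf_id	putative_function	host_gene_id	direction
330	DUF4326 domain-containing protein	XP_004336203.1	AtoV
349	Thioredoxin	XP_004340322.1	AtoV
375	DNA helicase	XP_004347213.1	AtoV
309	F-box domain-containing protein	XP_004337331.1	AtoV
412	Ser/Thr protein kinase	XP_004347234.1	AtoV
106	Linker histone H1	XP_004337841.1	AtoV
224	Ribonuclease HII	XP_004332877.1	AtoV
138	PIN domain-containing protein	XP_004339581.1	AtoV
139	BTB/POZ domain-containing protein	XP_004356555.1	AtoV
439	Transcription elongation factor S-II	XP_004339821.1	AtoV
204	BTB/POZ domain-containing protein	XP_004334604.1	AtoV
365	Replication factor C large subunit	XP_004357147.1	AtoV
111	Hypothetical protein	XP_004334601.1	VtoA
329	Putative myristoylated membrane protein	XP_004339071.1	VtoA
429	Hypothetical protein	XP_004335825.1	VtoA
188	Hypothetical protein	XP_004336714.1	VtoA
308	Hypothetical protein	XP_004335814.1	VtoA
261	Hypothetical protein	XP_004339028.1	VtoA
226	Putative membrane protein	XP_004339025.1	VtoA
454	PAN domain-containing protein	XP_004339817.1	VtoA
229	Putative VV A32-like packaging ATPase	XP_004335550.1	VtoA
177	Major capsid protein	XP_004336719.1	VtoA
203	Molybdenum cofactor carrier	XP_004340814.1	VtoA
282	Class 3 lipase	XP_004339082.1	VtoA
154	Hypothetical protein	XP_004347217.1	VtoA
210	Hypothetical protein	XP_004333492.1	Undetermined
351	Hypothetical protein	XP_004347207.1	Undetermined
354	Hypothetical protein	XP_004347218.1	Undetermined
199	Hypothetical protein	XP_004338290.1	Undetermined
200	Hypothetical protein	XP_004335813.1	Undetermined
290	Hypothetical protein	XP_004339813.1	Undetermined
186	Hypothetical protein	XP_004336716.1	Undetermined
236	Hypothetical protein	XP_004335548.1	Undetermined
134	Hypothetical protein	XP_004335826.1	Undetermined
310	Hypothetical protein	XP_004339029.1	Undetermined
178	Hypothetical protein	XP_004336720.1	Undetermined
179	Hypothetical protein	XP_004335539.1	Undetermined
74	Hypothetical protein	XP_004337837.1	Undetermined
103	Hypothetical protein	XP_004339001.1	Undetermined
5	Rho termination factor N-terminal domain-containing protein	XP_004337835.1	Undetermined
407	Hypothetical protein	XP_004340313.1	Undetermined
403	Hypothetical protein	XP_004335821.1	Undetermined
404	Hypothetical protein	XP_004352648.1	Undetermined
405	Hypothetical protein	XP_004347220.1	Undetermined
23	Hypothetical protein	XP_004338755.1	Undetermined
225	Hypothetical protein	XP_004339084.1	Undetermined
156	F-box domain-containing protein	XP_004335809.1	Undetermined
213	Hypothetical protein	XP_004333493.1	Undetermined
214	Hypothetical protein	XP_004333494.1	Undetermined
438	Hypothetical protein	XP_004339822.1	Undetermined
285	Hypothetical protein	XP_004340318.1	Undetermined
369	Hypothetical protein	XP_004339083.1	Undetermined
357	Hypothetical protein	XP_004347215.1	Undetermined
452	Hypothetical protein	XP_004352718.1	Undetermined
421	Hypothetical protein	XP_004335432.1	Undetermined
281	Hypothetical protein	XP_004334602.1	Undetermined
62	Hypothetical protein	XP_004337997.1	Undetermined
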