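ncvog_id	orf_id	ncvog_annotation	functional_category
NCVOG0038	411	DNA polymerase elongation subunit family B	DNA replication, recombination, and repair
NCVOG0023	368, 409	D5-like helicase-primase	DNA replication, recombination, and repair
NCVOG0278	192	RuvC, Holliday junction resolvases (HJRs); poxvirus A22 family	DNA replication, recombination, and repair
NCVOG1192	71	YqaJ viral recombinase	DNA replication, recombination, and repair
NCVOG1164	420	A1L transcription factor/late transcription factor VLTF2	Transcription and RNA processing
NCVOG0262	196	Poxvirus late transcription factor VLTF3 like	Transcription and RNA processing
NCVOG0272	439	Transcription factor S-II (TFIIS)	Transcription and RNA processing
NCVOG0276	287	Ribonucleoside diphosphate reductase, beta subunit	Nucleotide metabolism
NCVOG1353	279	Ribonucleoside diphosphate reductase, alpha subunit	Nucleotide metabolism
NCVOG0320	41	Thymidylate kinase	Nucleotide metabolism
NCVOG1068	348	dUTPase	Nucleotide metabolism
NCVOG0022	177	NCLDV major capsid protein	Virion structure and morphogenesis
NCVOG0249	37, 229, 302	Packaging ATPase	Virion structure and morphogenesis
NCVOG0211	329	Myristoylated IMV envelope protein	Virion structure and morphogenesis
NCVOG0040	209	Dual-specificity phosphatases (DSP); Ser/Thr and Tyr protein phosphatases	Other metabolic functions
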