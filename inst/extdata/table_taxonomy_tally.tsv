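class	n
eukaryotic	115
viral	45
prokaryotic	18
unclassified	4
ORFan	279
host_amoeba_closest	86
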