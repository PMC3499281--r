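category	n_scaffolds	length_mb	n_usnps
discordant	100	6.9	149
noinfo	197	1.2	213
nosynt	187	5.0	249
sscvalid	166	12.4	242
valid	778	53.7	1094
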