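era	n_genes
Ancient	14845
Metazoan	2253
Chordate	1584
Mammal	685
Primate	2069
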