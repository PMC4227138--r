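# log2 fold-changes with per-gene variances for the toy network
gene	log2fc	variance
g1	1.0	0.01
g2	1.0	0.01
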