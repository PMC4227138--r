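# minimal two-layer example: backbone a -> b, one downstream gene each
source	target	sign	layer_target	weight
a	b	+1	backbone	1
a	g1	+1	transcript	1
b	g2	+1	transcript	1
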