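gene	log2fc	padj
g1	-1	0.001
g2	1	0.001
g3	0.1	0.5
g4	-1	0.001
g5	-0.55	0.5
g6	-2	0.01
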