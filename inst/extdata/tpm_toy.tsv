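gene	condition	tpm
g1	a	10
g2	a	10
g3	a	10
g4	a	2
g5	a	10
g6	a	10
g1	b	10
g2	b	10
g3	b	10
g4	b	2
g5	b	10
g6	b	10
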