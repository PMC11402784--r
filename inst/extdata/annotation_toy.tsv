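gene	utr_length	biotype
g1	500	protein_coding
g2	500	protein_coding
g3	500	protein_coding
g4	500	protein_coding
g5	500	protein_coding
g6	50	protein_coding
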