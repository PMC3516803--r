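class	A	C	G	U
background	66	27	21	214
AGO1	0	6	1	63
AGO2	21	0	1	3
AGO4	5	0	0	4
AGO5	0	6	0	16
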