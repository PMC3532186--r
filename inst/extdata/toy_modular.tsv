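# synthetic toy modular network: two dense modules (A-D clique, E-G triangle) joined by one bridge
A	B
A	C
A	D
B	C
B	D
C	D
D	E
E	F
E	G
F	G
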