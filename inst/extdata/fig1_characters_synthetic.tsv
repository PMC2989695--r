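B	3,4,5
y	1,2
A	6
C	7
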