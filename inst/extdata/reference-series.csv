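x
0.1
0.3
1.2
0.2
0.8
1.7
1.3
0.4
0.2
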