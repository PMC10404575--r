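delta_I,f
0.5,2.16
1,2.3
2,2.6
4,3.75
6,3.92
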