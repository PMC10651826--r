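1 0 0.35
5 0 0.35
2 1 0.35
0 1 0.35
3 2 0.35
1 2 0.35
4 3 0.35
5 3 0.35
5 4 0.35
3 4 0.35
0 5 0.35
4 5 0.35
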