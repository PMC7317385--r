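pc,eigenvalue
1,2.145
2,0.157
3,0.072
4,0.022
5,0.017
6,0.010
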