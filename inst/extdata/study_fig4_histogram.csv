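ill_advised_coa,patients
0,195
1,48
2,19
3,6
4,2
6,1
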