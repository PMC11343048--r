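rhythm,patients,analyses,shock_advised,no_shock_advised,performance_pct,lcl90_pct,goal_pct
VF,260,692,657,35,94.9,93.7,90
NSR,12,16,0,16,100,100,99
ONR,167,1085,8,1077,99.3,99.0,95
ASYS,112,619,2,617,99.7,99.4,95
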