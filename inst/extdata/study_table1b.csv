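stage,rhythm,patients,analyses,shock_advised,no_shock_advised,performance_pct,lcl90_pct
STANDARD,VF,252,283,283,0,100,100
STANDARD,NSR,12,16,0,16,100,100
STANDARD,ONR,95,155,5,150,96.8,93.6
STANDARD,ASYS,52,84,2,82,97.6,92.8
STEP1,VF,162,409,380,29,92.9,90.3
STEP1,NSR,0,0,0,0,NA,NA
STEP1,ONR,162,930,45,885,95.2,94.4
STEP1,ASYS,109,535,72,463,86.5,84.2
STEP2,VF,161,380,374,6,98.4,97.5
STEP2,NSR,0,0,0,0,NA,NA
STEP2,ONR,37,45,3,42,93.3,78.8
STEP2,ASYS,48,72,0,72,100,100
SEQUENCE,VF,162,409,374,35,91.4,88.7
SEQUENCE,NSR,0,0,0,0,NA,NA
SEQUENCE,ONR,162,930,3,927,99.7,99.5
SEQUENCE,ASYS,109,535,0,535,100,100
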