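quantity,value
patients_enrolled,285
sas_decisions_total,3144
standard_analyses,576
step1_analyses,2011
step2_analyses,557
ill_advised_coa,118
ill_advised_handsoff_median_s,10
ill_advised_handsoff_q1_s,10
ill_advised_handsoff_q3_s,12
patients_step1,271
patients_step2,205
patients_any_ill_advised,76
fine_vf_shock_advice,78
fine_vf_shock_advice_pct,75
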