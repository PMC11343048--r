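metric,awc_value,awc_num,awc_den,cpri_value,cpri_num,cpri_den
patients,285,NA,NA,365,NA,NA
analysis_strips,2412,NA,NA,726,NA,NA
step1_duration_s,16,NA,NA,30,NA,NA
step2_duration_s,5,NA,NA,10,NA,NA
confirmation_rate_pct,27.7,557,2011,29.6,215,726
standard_vf_se_pct,100,283,283,NA,NA,NA
standard_nsr_sp_pct,100,16,16,NA,NA,NA
standard_onr_sp_pct,96.8,150,155,NA,NA,NA
standard_asys_sp_pct,97.6,82,84,NA,NA,NA
step1_vf_se_pct,92.9,380,409,81.8,90,110
step1_onr_sp_pct,95.2,885,930,78.2,169,216
step1_asys_sp_pct,86.5,463,535,60.3,240,398
step2_vf_se_pct,98.4,374,380,100,15,15
step2_onr_sp_pct,93.3,42,45,97.8,46,47
step2_asys_sp_pct,100,72,72,97.4,148,152
sequence_vf_se_pct,91.4,374,409,95.4,105,110
sequence_onr_sp_pct,99.7,927,930,99.5,215,216
sequence_asys_sp_pct,100,535,535,97.5,388,398
sequence_accuracy_pct,98.0,1836,1874,97.8,708,724
global_vf_se_pct,94.9,657,692,NA,NA,NA
global_nsr_sp_pct,100,16,16,NA,NA,NA
global_onr_sp_pct,99.3,1077,1085,NA,NA,NA
global_asys_sp_pct,99.7,617,619,NA,NA,NA
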