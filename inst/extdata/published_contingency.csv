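contrast,variable,exposed_case,exposed_ref,unexposed_case,unexposed_ref,printed_or,printed_ci_low,printed_ci_high
any_oa_vs_wt,sex_female,108,29,125,63,1.88,1.13,3.12
any_oa_vs_wt,pleural_metastasis,53,11,180,81,2.17,1.08,4.37
any_oa_vs_wt,cluster_m1,39,6,101,64,4.12,1.65,10.28
any_oa_vs_wt,cluster_m2m5,93,22,101,64,2.68,1.53,4.69
soa_vs_wt,cluster_m1,34,6,77,64,4.71,1.86,11.93
soa_vs_wt,pleural_metastasis,40,11,134,81,2.2,1.07,4.53
nsoa_vs_wt,never_smoker,25,7,22,83,13.47,5.15,35.22
nsoa_vs_wt,brain_metastasis,23,26,24,66,2.43,1.17,5.05
nsoa_vs_wt,bone_metastasis,32,42,15,50,2.54,1.21,5.31
nsoa_vs_soa,never_smoker,25,6,22,166,31.44,11.61,85.1
nsoa_vs_soa,sex_female,31,68,16,106,3.02,1.54,5.94
nsoa_vs_soa,peritoneal_metastasis,0,21,47,153,0,NA,NA
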