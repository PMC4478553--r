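study,method,n_samples,n_cnvrs,median_kb,mean_kb,total_mb,overlap_count,count_pct,overlap_len_kb,length_pct
ref_study_01,aCGH_385k,12,37,6.89,9.32,0.43,1,0.13,7.37,0.02
ref_study_02,SNP_60k,55,49,170.96,754.59,36.97,3,0.40,256.7,0.54
ref_study_03,SNP_60k,474,382,142.90,250.69,95.76,10,1.32,678.1,1.43
ref_study_04,aCGH_720k,12,259,98.74,65.07,16.85,55,7.26,1824.2,3.85
ref_study_05,SNP_60k,1693,565,252.71,247.55,139.87,106,13.98,10387.7,21.90
ref_study_06,sequencing,117,1928,3.00,5.23,10.08,165,21.77,5217.3,11.00
ref_study_07,SNP_60k,14,63,97.85,158.37,9.98,14,1.85,2178.3,4.59
ref_study_08,sequencing,16,3118,10.00,12.74,39.72,210,27.70,10996.4,27.18
ref_study_09,aCGH_2.1M,12,1344,11.11,35.56,47.79,283,37.33,21178.6,44.65
ref_study_10,sequencing_RD,13,3131,18.33,32.84,102.8,467,61.61,29910.8,63.06
this_study,aCGH_1M,12,758,20.93,62.57,47.43,NA,NA,NA,NA
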