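population,treatment,chase_temp_c,mmr_mean,mmr_sem,rmr_mean,rmr_sem,aas_mean,aas_sem,fas_mean,fas_sem,ctmax_mean,ctmax_sem
Lower Deschutes,18-22,19,10.62,0.54,2.85,0.12,7.78,0.61,3.76,0.25,32.06,0.08
Lower Deschutes,20-24,22,12.72,0.29,3.88,0.24,8.84,0.29,3.34,0.15,31.43,0.06
Lower Deschutes,23-27,26,12.59,0.56,4.60,0.21,7.99,0.47,2.76,0.12,31.31,0.11
John Day,14-27,19,12.85,0.89,2.42,0.10,10.42,0.91,5.42,0.47,31.22,0.07
John Day,20-24,22,15.23,0.99,4.13,0.28,11.09,0.83,3.72,0.20,NA,NA
John Day,23-27,27,12.89,1.74,6.56,1.08,6.32,1.11,2.21,0.33,31.16,0.08
Siletz,15-19,16,12.27,0.55,1.72,0.09,10.55,0.50,7.17,0.36,28.84,0.09
Siletz,18-22,19,13.86,0.66,2.72,0.23,11.14,0.49,5.25,0.23,29.50,0.11
Siletz,20-24,22,12.28,1.45,3.19,0.28,9.10,1.49,4.02,0.48,30.24,0.09
Siletz,23-26,25,11.06,0.52,4.70,0.26,6.36,0.33,2.36,0.07,NA,NA
North Umpqua,16-19,16,9.76,0.46,1.94,0.09,7.82,0.49,5.17,0.37,30.04,0.33
North Umpqua,18-22,19,10.20,0.47,2.37,0.05,7.83,0.48,4.33,0.22,29.88,0.25
North Umpqua,20-24,22,10.15,0.64,3.08,0.09,7.07,0.64,3.31,0.21,30.03,0.25
North Umpqua,23-26,25,9.54,0.38,3.84,0.18,5.70,0.35,2.52,0.11,29.91,0.38
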