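population,t_opt,t_pej_lower,t_pej_upper,t_fas3,ctmax_ambient,max_stream_temp,tsm,fwt
Lower Deschutes,NA,NA,NA,24.4,32.1,24.9,7.2,-0.5
John Day,21.3,17.4,25.2,24.9,31.2,27.1,4.1,-2.2
North Umpqua,17.4,11.0,23.7,23.3,30.0,21.6,8.4,1.7
Siletz,17.9,13.0,22.7,23.8,28.8,15.9,12.9,7.9
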