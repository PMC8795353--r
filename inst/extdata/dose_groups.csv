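radiation,cell_line,n_samples,mean_dose_gy,dose_error_gy,lateral_variation_pct,sample_variation_pct,n_shots,total_duration_s,rep_rate_hz
x-ray,RWPE1/PC3,5,0.5,0.3,1,NA,NA,24,NA
x-ray,RWPE1/PC3,5,1.0,0.3,1,NA,NA,48,NA
x-ray,RWPE1/PC3,6,2.1,0.3,1,NA,NA,93,NA
x-ray,RWPE1/PC3,5,5.3,0.4,1,NA,NA,228,NA
x-ray,RWPE1/PC3,5,8.3,0.4,1,NA,NA,362,NA
x-ray,RWPE1/PC3,5,10.5,0.6,1,NA,NA,450,NA
proton,RWPE1,6,8.5,3.4,27,25.9,10,50,0.2
proton,PC3,6,7.4,2.9,29,21.1,10,50,0.2
proton,RWPE1,6,15.8,3.3,16,11.4,16,80,0.2
proton,PC3,6,14.0,4.1,16,23.4,16,80,0.2
proton,RWPE1,6,21.0,4.4,15,13.4,20,100,0.2
proton,PC3,6,20.5,3.5,15,5.7,20,100,0.2
proton,RWPE1,4,37.1,7.1,18,7.5,30,150,0.2
proton,PC3,4,33.9,6.4,18,6.2,30,150,0.2
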