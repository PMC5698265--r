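# Published group summary statistics (mean, sample SD, n) from the source
# stereological study of hippocampal capillaries in a rat chronic
# unpredictable stress (CUS) model with treadmill running.
# phase: week4 = after model induction; week8 = after the running period.
# units: percent (sucrose preference), mm3, m, cm2.
metric,region,group,phase,n,mean,sd,unit
sucrose_preference,,control,week4,10,94.5,3.24,percent
sucrose_preference,,cus,week4,90,76.9,8.16,percent
sucrose_preference,,cus_standard,week8,10,79.7,13.3,percent
sucrose_preference,,cus_running,week8,10,91.5,4.83,percent
region_volume,CA1,control,week8,10,33.9,3.01,mm3
region_volume,CA1,cus_standard,week8,10,29.2,2.27,mm3
region_volume,CA1,cus_running,week8,10,32.0,2.66,mm3
region_volume,DG,control,week8,10,24.9,2.52,mm3
region_volume,DG,cus_standard,week8,10,21.0,1.62,mm3
region_volume,DG,cus_running,week8,10,23.3,2.84,mm3
cap_length,CA1,control,week8,10,11.7,1.15,m
cap_length,CA1,cus_standard,week8,10,9.67,0.92,m
cap_length,CA1,cus_running,week8,10,10.8,0.976,m
cap_length,DG,control,week8,10,10.9,1.03,m
cap_length,DG,cus_standard,week8,10,9.38,0.688,m
cap_length,DG,cus_running,week8,10,10.4,0.979,m
cap_volume,CA1,control,week8,10,0.157,0.0130,mm3
cap_volume,CA1,cus_standard,week8,10,0.111,0.0180,mm3
cap_volume,CA1,cus_running,week8,10,0.144,0.0160,mm3
cap_volume,DG,control,week8,10,0.155,0.0110,mm3
cap_volume,DG,cus_standard,week8,10,0.115,0.0300,mm3
cap_volume,DG,cus_running,week8,10,0.143,0.0180,mm3
cap_surface,CA1,control,week8,10,1.40,0.204,cm2
cap_surface,CA1,cus_standard,week8,10,1.06,0.117,cm2
cap_surface,CA1,cus_running,week8,10,1.29,0.184,cm2
cap_surface,DG,control,week8,10,1.40,0.151,cm2
cap_surface,DG,cus_standard,week8,10,1.11,0.135,cm2
cap_surface,DG,cus_running,week8,10,1.25,0.177,cm2
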