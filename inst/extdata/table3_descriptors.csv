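parameter,units,control_mean,control_sd,fracture_mean,fracture_sd
aBMD,g/cm2,0.85,0.12,0.76,0.11
integral_vBMD,mg/cm3,290.17,47.92,252.23,41.22
trab_vBMD,mg/cm3,140.39,34.94,112.2,28.54
cortical_sBMD,mg/cm2,144.13,18.90,131.30,18.21
F0_N,N,3407.70,568.3,2984.82,552.81
D0_mm,mm,2.67,0.28,2.98,0.31
E_nl_Nmm,N.mm,6588.48,1197.23,6504.74,1248.04
F1_N,N,2707.66,469.18,2351.17,446.46
D1_mm,mm,0.92,0.06,0.97,0.06
E_lin_Nmm,N.mm,1250.07,216.58,1139.39,211.78
D2_mm,mm,1.75,0.23,2.01,0.28
D3_mm,mm,1.50,0.21,1.74,0.23
E_dis_Nmm,N.mm,4579.60,875.13,4621.86,885.90
E_res_Nmm,N.mm,1983.11,335.87,1839.58,342.28
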