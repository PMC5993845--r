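calibration,condition,n_scans,mean_sbr,min_sbr,max_sbr,slope,intercept,icc,icc_lo,icc_hi
original,CTACSC,292,9.12,4.41,14.31,1.200,2.334,0.438,-0.096,0.781
original,ChangACSC,510,10.48,5.41,19.08,1.445,2.138,0.333,-0.075,0.698
original,CTACNOSC,292,6.72,3.32,11.46,0.996,1.091,0.860,-0.126,0.963
original,ChangACNOSC,510,7.09,3.40,12.21,1.121,0.618,0.808,-0.159,0.945
original,NOACNOSC,510,5.77,2.18,10.94,NA,NA,NA,NA,NA
calibrated,CTACSC,292,8.96,4.37,13.76,1.053,0.517,0.832,0.372,0.928
calibrated,ChangACSC,510,9.31,4.10,17.05,1.103,0.297,0.820,0.222,0.928
calibrated,CTACNOSC,292,7.63,3.35,11.83,0.825,1.011,0.926,0.839,0.959
calibrated,ChangACNOSC,510,7.95,3.97,14.66,0.927,0.380,0.958,0.940,0.969
calibrated,NOACNOSC,510,8.16,3.81,13.89,NA,NA,NA,NA,NA
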