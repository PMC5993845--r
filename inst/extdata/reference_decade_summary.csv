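group,decade,n_subjects,n_scans,sbr_mean,sbr_lower_pi,ai_mean,ai_upper_pi
both,30-39,45,90,9.52,6.82,3.59,10.53
both,40-49,43,86,8.91,6.22,3.88,10.81
both,50-59,39,78,8.31,5.62,4.17,11.09
both,60-69,71,142,7.71,5.01,4.46,11.38
both,70-79,48,95,7.10,4.41,4.75,11.68
both,80-89,10,19,6.50,3.80,5.04,11.99
M,30-39,30,60,9.01,6.36,3.40,10.58
M,40-49,15,30,8.53,5.89,3.93,11.09
M,50-59,17,34,8.05,5.41,4.46,11.61
M,60-69,31,62,7.57,4.93,4.98,12.14
M,70-79,18,35,7.09,4.44,5.51,12.69
M,80-89,5,9,6.61,3.95,6.04,13.25
F,30-39,15,30,10.11,7.46,3.81,10.55
F,40-49,28,56,9.35,6.71,3.91,10.62
F,50-59,22,44,8.58,5.95,4.00,10.71
F,60-69,40,80,7.82,5.18,4.10,10.81
F,70-79,30,60,7.06,4.42,4.20,10.92
F,80-89,5,10,6.30,3.64,4.30,11.05
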