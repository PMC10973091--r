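construct,subunit,background,glu_ec50,glu_lo,glu_hi,glu_n,glu_sig,gly_ec50,gly_lo,gly_hi,gly_n,gly_sig,mg_ic50,mg_lo,mg_hi,mg_n,mg_sig,mg_censored,ph_pct,ph_sem,ph_n,ph_sig,surf_ratio,surf_sem,surf_n,surf_sig
WT GluN1/2A,WT,2A,3.5,3.4,3.6,113,FALSE,1.2,1.1,1.2,122,FALSE,19,17,20,113,FALSE,FALSE,43,0.7,118,FALSE,1.0,NA,36,FALSE
1-A637S/2A,GluN1,2A,3.9,3.1,4.8,12,FALSE,0.74,0.67,0.82,12,TRUE,48,41,55,11,TRUE,FALSE,50,1.9,11,FALSE,0.87,0.44,3,FALSE
1-A637V/2A,GluN1,2A,2.8,2.3,3.2,12,TRUE,1.0,0.88,1.2,12,FALSE,347,257,469,12,TRUE,FALSE,39,1.6,12,FALSE,1.3,0.09,4,TRUE
1-G638A/2A,GluN1,2A,2.4,2.1,2.7,12,TRUE,0.88,0.80,0.96,14,TRUE,46,34,62,11,TRUE,FALSE,53,8.1,12,TRUE,1.4,0.12,4,TRUE
1-G638V/2A,GluN1,2A,1.3,1.2,1.4,12,TRUE,0.48,0.43,0.54,12,TRUE,435,363,522,18,TRUE,FALSE,52,1.4,16,TRUE,0.47,0.12,5,TRUE
1-M641I/2A,GluN1,2A,3.4,2.6,4.2,15,FALSE,1.1,1.0,1.2,19,FALSE,161,118,204,19,TRUE,FALSE,41,0.22,22,FALSE,0.71,0.10,5,TRUE
1-M641L/2A,GluN1,2A,1.2,0.82,1.9,17,TRUE,0.58,0.49,0.69,18,TRUE,13,9.6,18,14,FALSE,FALSE,73,1.2,25,TRUE,0.88,0.08,4,FALSE
1-M641V/2A,GluN1,2A,2.5,2.2,2.9,12,TRUE,0.85,0.73,0.99,12,TRUE,31,27,35,12,TRUE,FALSE,50,1.2,12,TRUE,1.3,0.11,6,FALSE
1-I642L/2A,GluN1,2A,8.6,8.0,9.1,12,TRUE,2.0,1.9,2.2,12,TRUE,21,19,23,12,FALSE,FALSE,21,1.6,12,TRUE,0.78,0.09,4,TRUE
1-I642T/2A,GluN1,2A,7.1,6.5,7.7,12,TRUE,2.3,2.1,2.5,12,TRUE,17,13,21,12,FALSE,FALSE,35,1.6,12,TRUE,1.8,0.55,3,FALSE
1-I643V/2A,GluN1,2A,1.9,1.7,2.1,12,TRUE,0.73,0.63,0.86,12,TRUE,23,16,32,12,FALSE,FALSE,60,2.4,12,TRUE,0.84,0.03,6,FALSE
1-V644M/2A,GluN1,2A,0.30,0.25,0.36,12,TRUE,0.14,0.11,0.18,12,TRUE,38,31,46,14,TRUE,FALSE,82,2.3,12,TRUE,1.0,0.09,4,FALSE
1-A645S/2A,GluN1,2A,3.2,3.0,3.5,18,FALSE,1.0,0.88,1.1,15,FALSE,41,32,52,12,TRUE,FALSE,62,2.4,24,TRUE,0.79,0.21,5,FALSE
1-Y647C/2A,GluN1,2A,0.08,0.05,0.12,16,TRUE,0.023,0.014,0.037,14,TRUE,6.0,5.2,7.0,23,TRUE,FALSE,34,1.3,31,TRUE,0.24,0.02,4,TRUE
1-Y647S/2A,GluN1,2A,0.069,0.05,0.10,15,TRUE,0.043,0.033,0.058,17,TRUE,12,6.7,20,5,FALSE,FALSE,27,1.1,26,TRUE,0.16,0.05,4,TRUE
1-N650I/2A,GluN1,2A,0.037,0.026,0.053,12,TRUE,0.046,0.034,0.062,16,TRUE,8.3,6.5,11,12,TRUE,FALSE,47,1.4,12,FALSE,0.76,0.12,4,TRUE
1-N650K/2A,GluN1,2A,0.46,0.36,0.59,11,TRUE,0.22,0.20,0.24,12,TRUE,46,40,53,14,TRUE,FALSE,39,3.1,12,FALSE,0.055,0.012,5,TRUE
1-A652T/2A,GluN1,2A,4.0,3.4,4.7,24,FALSE,1.0,0.95,1.1,14,FALSE,19,15,23,18,FALSE,FALSE,23,1.2,18,TRUE,1.1,0.16,6,FALSE
1-A653G/2A,GluN1,2A,0.15,0.12,0.17,11,TRUE,0.12,0.090,0.14,12,TRUE,22,18,29,13,FALSE,FALSE,37,3.0,14,FALSE,0.023,0.004,6,TRUE
1-A653T/2A,GluN1,2A,0.12,0.10,0.14,14,TRUE,0.024,0.019,0.031,12,TRUE,23,18,30,12,FALSE,FALSE,88,1.3,11,TRUE,1.1,0.08,4,FALSE
1-F654C/2A,GluN1,2A,0.26,0.21,0.32,12,TRUE,0.13,0.11,0.15,12,TRUE,22,18,27,12,FALSE,FALSE,46,1.5,12,FALSE,1.4,0.13,4,TRUE
1-L655Q/2A,GluN1,2A,0.34,0.32,0.35,16,TRUE,0.095,0.080,0.11,15,TRUE,18,15,20,8,FALSE,FALSE,46,0.5,12,FALSE,0.86,0.04,5,TRUE
2A-S632F,GluN2A,2A,3.6,3.2,4.0,12,FALSE,1.4,1.3,1.5,12,TRUE,93,74,116,11,TRUE,FALSE,37,1.4,12,FALSE,0.96,0.157,8,FALSE
2A-A635T,GluN2A,2A,0.96,0.83,1.1,12,TRUE,0.28,0.23,0.33,12,TRUE,56,42,76,12,TRUE,FALSE,60,1.7,14,TRUE,0.76,0.26,10,FALSE
2A-V639I,GluN2A,2A,0.53,0.46,0.61,14,TRUE,0.26,0.23,0.31,12,TRUE,33,27,41,12,TRUE,FALSE,82,2.7,14,TRUE,1.21,0.26,6,FALSE
2A-L642M,GluN2A,2A,0.61,0.43,0.86,13,TRUE,0.36,0.28,0.47,12,TRUE,35,27,44,12,TRUE,FALSE,94,0.78,13,TRUE,0.37,0.02,4,TRUE
2A-L642R,GluN2A,2A,0.87,0.75,1.0,14,TRUE,0.31,0.28,0.34,14,TRUE,1000,NA,NA,13,TRUE,TRUE,73,2.5,14,TRUE,0.10,0.05,4,TRUE
2A-A643D,GluN2A,2A,1.0,0.70,1.4,23,TRUE,0.11,0.093,0.13,13,TRUE,39,28,56,12,TRUE,FALSE,48,1.5,13,FALSE,0.44,0.06,4,TRUE
2A-S644G,GluN2A,2A,0.17,0.13,0.22,21,TRUE,0.076,0.047,0.094,14,TRUE,33,27,35,26,TRUE,FALSE,97,1.2,19,TRUE,0.34,0.10,4,TRUE
2A-T646A,GluN2A,2A,0.14,0.08,0.24,12,TRUE,0.071,0.058,0.087,14,TRUE,35,26,47,12,TRUE,FALSE,84,2.7,12,TRUE,0.041,0.02,5,TRUE
2A-T646R,GluN2A,2A,0.21,0.13,0.34,6,TRUE,0.0068,0.0026,0.018,6,TRUE,1000,NA,NA,6,TRUE,TRUE,92,1.9,12,TRUE,0.91,0.09,6,FALSE
2A-N648S,GluN2A,2A,1.3,1.1,1.4,16,TRUE,0.45,0.36,0.57,12,TRUE,15,12,18,13,FALSE,FALSE,25,0.7,16,TRUE,0.27,0.09,6,TRUE
2A-L649V,GluN2A,2A,0.035,0.022,0.056,11,TRUE,0.012,0.0075,0.020,8,TRUE,69,58,81,8,TRUE,FALSE,97,2.0,18,TRUE,0.34,0.03,4,TRUE
2A-A650S,GluN2A,2A,2.8,2.5,3.1,12,TRUE,0.80,0.70,0.91,12,TRUE,41,32,53,8,TRUE,FALSE,68,1.5,10,TRUE,0.47,0.16,5,TRUE
2A-F652V,GluN2A,2A,0.93,0.78,1.1,12,TRUE,0.65,0.54,0.78,8,TRUE,187,154,228,16,TRUE,FALSE,16,2.2,12,TRUE,0.86,0.09,4,FALSE
2A-M653I,GluN2A,2A,0.17,0.14,0.20,14,TRUE,0.062,0.048,0.082,13,TRUE,11,10,13,12,TRUE,FALSE,19,1.2,12,TRUE,0.29,0.03,4,TRUE
2A-M653V,GluN2A,2A,0.058,0.040,0.084,19,TRUE,0.055,0.042,0.071,11,TRUE,62,44,87,17,TRUE,FALSE,32,2.5,27,TRUE,0.51,0.19,3,TRUE
2A-I654T,GluN2A,2A,0.016,0.007,0.034,14,TRUE,0.061,0.052,0.072,12,TRUE,30,23,38,12,TRUE,FALSE,68,1.5,19,TRUE,0.22,0.06,4,TRUE
WT GluN1/2B,WT,2B,1.2,1.1,1.2,66,FALSE,0.39,0.35,0.44,62,FALSE,22,20,25,59,FALSE,FALSE,16,0.5,93,FALSE,1.0,NA,10,FALSE
1-G638V/2B,GluN1,2B,0.92,0.74,1.1,16,FALSE,0.20,0.17,0.23,12,TRUE,296,150,581,7,TRUE,FALSE,13,0.8,30,FALSE,0.57,0.11,4,TRUE
1-M641I/2B,GluN1,2B,1.5,1.0,2.1,11,FALSE,0.27,0.14,0.41,13,FALSE,408,222,594,15,TRUE,FALSE,14,0.9,13,FALSE,1.1,0.12,6,FALSE
1-A645S/2B,GluN1,2B,1.6,1.4,1.8,12,FALSE,0.45,0.35,0.59,13,FALSE,67,50,90,12,TRUE,FALSE,20,1.2,17,FALSE,1.0,0.15,6,FALSE
1-Y647C/2B,GluN1,2B,0.034,0.02,0.06,9,TRUE,0.0233,0.014,0.037,14,TRUE,14,10,20,10,FALSE,FALSE,30,2.8,12,TRUE,0.58,0.09,4,TRUE
1-N650K/2B,GluN1,2B,0.052,0.046,0.059,12,TRUE,0.041,0.030,0.055,8,TRUE,33,27,39,12,TRUE,FALSE,19,0.6,12,FALSE,0.35,0.06,4,TRUE
1-A652T/2B,GluN1,2B,0.61,0.50,0.74,12,TRUE,0.12,0.10,0.13,8,TRUE,31,24,41,8,FALSE,FALSE,16,2.0,12,FALSE,0.70,0.10,4,FALSE
1-A653G/2B,GluN1,2B,0.17,0.13,0.21,24,TRUE,0.14,0.11,0.18,17,TRUE,36,26,49,16,TRUE,FALSE,15,0.5,20,FALSE,0.32,0.01,4,TRUE
1-L655Q/2B,GluN1,2B,0.28,0.27,0.30,6,TRUE,0.13,0.10,0.18,11,TRUE,24,18,34,6,FALSE,FALSE,33,0.8,12,TRUE,0.63,0.13,4,TRUE
2B-A636P,GluN2B,2B,NA,NA,NA,NA,FALSE,NA,NA,NA,NA,FALSE,NA,NA,NA,NA,FALSE,FALSE,NA,NA,NA,FALSE,0.068,0.02,4,TRUE
2B-A636V,GluN2B,2B,0.49,0.43,0.57,18,TRUE,0.15,0.14,0.17,14,TRUE,156,146,167,12,TRUE,FALSE,36,1.6,12,TRUE,0.36,0.08,10,TRUE
2B-A639V,GluN2B,2B,0.28,0.21,0.36,12,TRUE,0.065,0.050,0.086,12,TRUE,14,12,16,12,TRUE,FALSE,58,6.1,12,TRUE,0.13,0.07,4,TRUE
2B-I641T,GluN2B,2B,0.57,0.47,0.70,13,TRUE,0.15,0.13,0.18,12,TRUE,21,16,28,12,FALSE,FALSE,25,1.6,12,TRUE,0.48,0.09,4,TRUE
2B-Y646C,GluN2B,2B,0.22,0.17,0.30,14,TRUE,0.020,0.014,0.028,13,TRUE,30,27,34,12,TRUE,FALSE,23,2.4,12,FALSE,0.58,0.10,3,TRUE
2B-N649S,GluN2B,2B,0.10,0.071,0.15,6,TRUE,0.047,0.021,0.10,4,TRUE,23,21,26,10,FALSE,FALSE,16,0.9,12,FALSE,0.97,0.08,4,FALSE
2B-N649T,GluN2B,2B,0.10,0.077,0.14,16,TRUE,0.056,0.043,0.073,13,TRUE,29,25,33,15,FALSE,FALSE,14,1.2,15,FALSE,0.86,0.11,4,FALSE
2B-A652G,GluN2B,2B,1.4,1.1,1.7,15,FALSE,0.26,0.21,0.33,12,TRUE,63,44,82,12,TRUE,FALSE,40,0.9,15,TRUE,1.5,0.30,5,FALSE
2B-A652P,GluN2B,2B,4.1,3.5,4.9,15,TRUE,0.96,0.81,1.1,11,TRUE,19,13,28,12,FALSE,FALSE,37,3.2,12,TRUE,1.0,0.10,4,FALSE
2B-F653V,GluN2B,2B,NA,NA,NA,NA,FALSE,NA,NA,NA,NA,FALSE,NA,NA,NA,NA,FALSE,FALSE,NA,NA,NA,FALSE,NA,NA,NA,FALSE
2B-I655F,GluN2B,2B,1.3,1.1,1.5,20,FALSE,0.37,0.32,0.42,28,FALSE,22,18,27,24,FALSE,FALSE,67,2.5,22,TRUE,0.56,0.09,6,TRUE
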