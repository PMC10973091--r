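construct,subunit,background,wt_block,po,po_sem,po_n,po_sig,tau_w,tau_sem,tau_n,tau_sig,tau_status,amp,amp_sem,amp_n,ct_syn,ct_nonsyn
WT GluN1/2A,WT,2A,glun1_block,0.24,0.005,122,FALSE,44,2.2,37,FALSE,measured,153,20,36,1.0,1.0
1-A637S/2A,GluN1,2A,glun1_block,0.37,0.05,16,TRUE,55,4.1,7,FALSE,measured,169,43,7,3.4,2.3
1-A637V/2A,GluN1,2A,glun1_block,0.12,0.01,15,TRUE,67,8.8,5,FALSE,measured,194,49,5,13,15
1-G638A/2A,GluN1,2A,glun1_block,0.34,0.013,14,TRUE,88,13,5,FALSE,measured,147,46,5,3.4,5.1
1-G638V/2A,GluN1,2A,glun1_block,0.28,0.03,14,FALSE,194,8.7,6,FALSE,measured,117,37,6,39,26
1-M641I/2A,GluN1,2A,glun1_block,0.095,0.006,16,TRUE,65,6.7,6,FALSE,measured,73,21,6,3.6,2.2
1-M641L/2A,GluN1,2A,glun1_block,0.38,0.02,14,TRUE,95,7.8,6,FALSE,measured,139,13,6,4.0,11
1-M641V/2A,GluN1,2A,glun1_block,0.14,0.008,13,TRUE,49,4.3,5,FALSE,measured,139,24,5,1.8,3.5
1-I642L/2A,GluN1,2A,glun1_block,0.046,0.005,16,TRUE,23,3.8,5,FALSE,measured,191,50,5,0.11,0.075
1-I642T/2A,GluN1,2A,glun1_block,0.055,0.001,15,TRUE,27,3.9,6,FALSE,measured,50,22,5,0.26,0.17
1-I643V/2A,GluN1,2A,glun1_block,0.38,0.017,15,TRUE,163,84,5,FALSE,measured,66,40,5,5.7,5.9
1-V644M/2A,GluN1,2A,glun1_block,0.21,0.009,20,FALSE,1118,335,5,TRUE,measured,53,22,5,111,118
1-A645S/2A,GluN1,2A,glun1_block,0.34,0.02,14,TRUE,72,6.6,7,FALSE,measured,234,29,6,4.3,3.2
1-Y647C/2A,GluN1,2A,glun1_block,0.20,0.01,15,FALSE,NA,NA,NA,FALSE,n.d.,0.08,0.02,6,NA,5.3
1-Y647S/2A,GluN1,2A,glun1_block,0.027,0.004,22,TRUE,NA,NA,NA,FALSE,n.a.,NA,NA,NA,NA,1.2
1-N650I/2A,GluN1,2A,glun1_block,0.14,0.004,8,TRUE,1753,81,5,TRUE,measured,37,8.4,5,20,33
1-N650K/2A,GluN1,2A,glun1_block,0.050,0.005,26,TRUE,259,33,7,FALSE,measured,31,9.5,7,0.10,0.28
1-A652T/2A,GluN1,2A,glun1_block,0.12,0.02,25,TRUE,31,1.7,6,FALSE,measured,130,56,6,0.35,0.52
1-A653G/2A,GluN1,2A,glun1_block,0.40,0.05,13,TRUE,516,56,7,FALSE,measured,88,22,6,0.80,2.4
1-A653T/2A,GluN1,2A,glun1_block,0.45,0.01,16,TRUE,1034,276,5,TRUE,measured,86,16,5,58,114
1-F654C/2A,GluN1,2A,glun1_block,0.40,0.002,16,TRUE,351,63,5,FALSE,measured,90,21,5,16,53
1-L655Q/2A,GluN1,2A,glun1_block,0.23,0.007,31,FALSE,239,16,8,FALSE,measured,113,26,8,5.3,15
WT GluN1/2A (2A set),WT,2A,glun2a_block,0.19,0.007,84,FALSE,44,2.2,37,FALSE,measured,153,20,36,1.0,1.0
2A-S632F,GluN2A,2A,glun2a_block,0.065,0.003,10,TRUE,46,4.5,5,FALSE,measured,95,34,5,1.3,1.4
2A-A635T,GluN2A,2A,glun2a_block,0.70,0.03,10,TRUE,247,43,5,FALSE,measured,59,37,5,43,46
2A-V639I,GluN2A,2A,glun2a_block,0.99,0.02,14,TRUE,891,363,6,TRUE,measured,43,19,6,137,79
2A-L642M,GluN2A,2A,glun2a_block,0.55,0.04,25,TRUE,187,38,8,FALSE,measured,79,27,8,6.5,19
2A-L642R,GluN2A,2A,glun2a_block,0.17,0.01,12,FALSE,121,14,7,FALSE,measured,40,12,7,11,21
2A-A643D,GluN2A,2A,glun2a_block,0.39,0.02,20,TRUE,1015,214,9,TRUE,measured,46,20,9,56,28
2A-S644G,GluN2A,2A,glun2a_block,1.0,0.02,19,TRUE,1718,492,6,TRUE,measured,87,31,6,333,295
2A-T646A,GluN2A,2A,glun2a_block,0.64,0.09,9,TRUE,2059,124,9,TRUE,measured,72,6.2,9,8.2,6.7
2A-T646R,GluN2A,2A,glun2a_block,1.0,0.17,11,TRUE,1341,84,6,TRUE,measured,19,3.5,6,4772,5502
2A-N648S,GluN2A,2A,glun2a_block,0.013,0.003,15,TRUE,88,6.7,9,FALSE,measured,32,4.4,9,0.12,0.31
2A-L649V,GluN2A,2A,glun2a_block,0.77,0.03,26,TRUE,2934,990,8,TRUE,measured,5.5,1.4,8,329,304
2A-A650S,GluN2A,2A,glun2a_block,0.54,0.03,17,TRUE,168,44,5,FALSE,measured,97,87,5,8.2,4
2A-F652V,GluN2A,2A,glun2a_block,0.0018,0.0002,11,TRUE,97,8.7,8,FALSE,measured,21,17,8,0.13,0.31
2A-M653I,GluN2A,2A,glun2a_block,0.13,0.01,14,FALSE,75,8.9,7,FALSE,measured,105,25,7,0.21,4.3
2A-M653V,GluN2A,2A,glun2a_block,0.18,0.09,18,FALSE,795,40,7,FALSE,measured,28,7.6,7,26,74
2A-I654T,GluN2A,2A,glun2a_block,0.40,0.04,11,TRUE,948,74,7,TRUE,measured,24,9.9,7,11,31
WT GluN1/2B,WT,2B,glun2b_block,0.033,0.002,84,FALSE,524,23,26,FALSE,measured,55,9.7,26,1.0,1.0
2B-A636V,GluN2B,2B,glun2b_block,0.14,0.02,16,TRUE,NA,NA,NA,FALSE,n.d.,0.11,0.05,3,NA,23
2B-A639V,GluN2B,2B,glun2b_block,0.72,0.05,11,TRUE,7954,1726,5,TRUE,measured,7.2,2.0,5,7.9,6.2
2B-I641T,GluN2B,2B,glun2b_block,0.034,0.002,10,FALSE,950,134,16,FALSE,measured,33,3.7,16,0.55,1.0
2B-Y646C,GluN2B,2B,glun2b_block,0.034,0.003,16,FALSE,NA,NA,NA,FALSE,n.d.,0.12,0.04,7,NA,6.1
2B-N649S,GluN2B,2B,glun2b_block,0.017,0.004,22,FALSE,NA,NA,NA,FALSE,n.d.,0.27,0.08,5,NA,8.2
2B-N649T,GluN2B,2B,glun2b_block,0.016,0.005,20,FALSE,NA,NA,NA,FALSE,n.d.,0.47,0.15,6,NA,8.3
2B-A652G,GluN2B,2B,glun2b_block,0.12,0.03,14,TRUE,525,43,6,FALSE,measured,72,17,6,6.3,12
2B-A652P,GluN2B,2B,glun2b_block,0.0067,0.0003,20,FALSE,104,11,5,FALSE,measured,56,26,5,0.012,0.020
2B-I655F,GluN2B,2B,glun2b_block,0.31,0.01,16,TRUE,361,15,9,TRUE,measured,93,25,9,1.5,2.0
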