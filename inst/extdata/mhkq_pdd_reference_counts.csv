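item_id,n_endorsed,n_not_endorsed,pct_printed
MHKQ1,11547,990,92.10
MHKQ2,4962,7575,39.58
MHKQ3,9683,2854,77.24
MHKQ4,4951,7586,39.49
MHKQ5,9876,2661,78.77
MHKQ6,2449,10088,19.53
MHKQ7,9113,3424,72.69
MHKQ8,9498,3039,75.76
MHKQ9,3831,8706,30.56
MHKQ10,2304,10233,18.38
MHKQ11,10467,2070,83.49
MHKQ12,6418,6119,51.19
MHKQ13,1706,10831,13.61
MHKQ14,2195,10342,17.51
MHKQ15,5012,7525,39.98
MHKQ16,8374,4163,66.79
MHKQ17,6520,6017,52.01
MHKQ18,11290,1247,90.05
MHKQ19,5172,7365,41.25
MHKQ20,5550,6987,44.27
Stigma1,6195,6342,49.41
Stigma2,7983,4554,63.68
Stigma3,6500,6037,51.85
Stigma4,6454,6083,51.48
Stigma5,4152,8385,33.12
Stigma6,8178,4359,65.23
Stigma7,4978,7559,39.71
Stigma8,5559,6978,44.34
Stigma9,7479,5058,59.66
Stigma10,7986,4551,63.70
Stigma11,6506,6031,51.89
Stigma12,6009,6528,47.93
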