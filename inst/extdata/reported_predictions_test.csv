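model,sample_id,taken,found,pct_recovery
PLSR,V1,20,19.72,98.59
PLSR,V2,50,49.96,99.93
PLSR,V3,50,49.19,98.37
PLSR,V4,20,19.6,97.98
PLSR,V5,30,30.63,102.1
PLSR,V6,45,44.29,98.42
PLSR,V7,25,24.53,98.11
PLSR,V8,30,29.31,97.7
PLSR,V9,25,24.97,99.89
DPLSR,V1,20,19.39,96.96
DPLSR,V2,50,50.58,101.15
DPLSR,V3,50,50.24,100.49
DPLSR,V4,20,19.06,95.28
DPLSR,V5,30,30.48,101.61
DPLSR,V6,45,45.18,100.41
DPLSR,V7,25,27.47,109.88
DPLSR,V8,30,32.09,106.95
DPLSR,V9,25,25.23,100.94
OPLS-PLSR,V1,20,19.74,98.71
OPLS-PLSR,V2,50,50.58,101.16
OPLS-PLSR,V3,50,49.78,99.57
OPLS-PLSR,V4,20,19.59,97.96
OPLS-PLSR,V5,30,30.31,101.05
OPLS-PLSR,V6,45,44.95,99.89
OPLS-PLSR,V7,25,24.93,99.74
OPLS-PLSR,V8,30,29.92,99.74
OPLS-PLSR,V9,25,24.83,99.34
SVR,V1,20,20.12,100.58
SVR,V2,50,50.24,100.48
SVR,V3,50,49.61,99.22
SVR,V4,20,19.82,99.1
SVR,V5,30,30.1,100.34
SVR,V6,45,45.09,100.21
SVR,V7,25,24.89,99.58
SVR,V8,30,29.92,99.73
SVR,V9,25,24.64,98.54
DSVR,V1,20,20.28,101.38
DSVR,V2,50,50.36,100.72
DSVR,V3,50,49.64,99.28
DSVR,V4,20,20.36,101.8
DSVR,V5,30,29.64,98.8
DSVR,V6,45,44.64,99.2
DSVR,V7,25,25.36,101.44
DSVR,V8,30,30.36,101.2
DSVR,V9,25,25.36,101.44
OPLS-SVR,V1,20,20.05,100.27
OPLS-SVR,V2,50,50.21,100.42
OPLS-SVR,V3,50,49.79,99.58
OPLS-SVR,V4,20,19.79,98.95
OPLS-SVR,V5,30,30.21,100.7
OPLS-SVR,V6,45,44.79,99.53
OPLS-SVR,V7,25,24.87,99.48
OPLS-SVR,V8,30,29.89,99.62
OPLS-SVR,V9,25,24.79,99.16
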