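model,sample_id,taken,found,pct_recovery
PLSR,T1,20,19.45,97.25
PLSR,T2,20,19.9,99.52
PLSR,T3,30,30.09,100.31
PLSR,T4,30,30.53,101.75
PLSR,T5,60,59.6,99.33
PLSR,T6,30,30.08,100.27
PLSR,T7,20,19.83,99.15
PLSR,T8,50,50.23,100.45
PLSR,T9,50,49.94,99.89
PLSR,T10,30,30.57,101.9
PLSR,T11,50,49.44,98.88
PLSR,T12,20,19.92,99.61
PLSR,T13,60,59.87,99.79
PLSR,T14,60,59.84,99.73
PLSR,T15,50,50.33,100.66
PLSR,T16,60,60.37,100.62
DPLSR,T1,20,19.06,95.28
DPLSR,T2,20,20.08,100.39
DPLSR,T3,30,30.56,101.88
DPLSR,T4,30,29.96,99.87
DPLSR,T5,60,59.38,98.96
DPLSR,T6,30,29.99,99.97
DPLSR,T7,20,20.08,100.41
DPLSR,T8,50,50.63,101.27
DPLSR,T9,50,50.46,100.92
DPLSR,T10,30,30.25,100.84
DPLSR,T11,50,50.1,100.21
DPLSR,T12,20,19.97,99.84
DPLSR,T13,60,60.01,100.02
DPLSR,T14,60,60.01,100.01
DPLSR,T15,50,50.03,100.06
DPLSR,T16,60,59.43,99.05
OPLS-PLSR,T1,20,19.63,98.15
OPLS-PLSR,T2,20,20.02,100.1
OPLS-PLSR,T3,30,30.2,100.67
OPLS-PLSR,T4,30,30.26,100.87
OPLS-PLSR,T5,60,59.89,99.82
OPLS-PLSR,T6,30,30.11,100.37
OPLS-PLSR,T7,20,19.97,99.85
OPLS-PLSR,T8,50,50.18,100.36
OPLS-PLSR,T9,50,50.04,100.08
OPLS-PLSR,T10,30,30.4,101.33
OPLS-PLSR,T11,50,49.56,99.12
OPLS-PLSR,T12,20,19.83,99.15
OPLS-PLSR,T13,60,60.01,100.02
OPLS-PLSR,T14,60,59.94,99.9
OPLS-PLSR,T15,50,49.56,99.12
OPLS-PLSR,T16,60,60.38,100.63
SVR,T1,20,19.85,99.25
SVR,T2,20,20.15,100.75
SVR,T3,30,30.29,100.98
SVR,T4,30,30.15,100.5
SVR,T5,60,59.88,99.81
SVR,T6,30,30.15,100.49
SVR,T7,20,19.85,99.25
SVR,T8,50,50.07,100.14
SVR,T9,50,50.07,100.14
SVR,T10,30,30.15,100.5
SVR,T11,50,49.62,99.25
SVR,T12,20,19.85,99.25
SVR,T13,60,60.09,100.16
SVR,T14,60,60,100
SVR,T15,50,50.08,100.17
SVR,T16,60,60.15,100.25
DSVR,T1,20,19.34,96.7
DSVR,T2,20,20.36,101.8
DSVR,T3,30,30.64,102.14
DSVR,T4,30,30.25,100.82
DSVR,T5,60,59.29,98.82
DSVR,T6,30,30.17,100.57
DSVR,T7,20,19.64,98.2
DSVR,T8,50,50.54,101.09
DSVR,T9,50,50.36,100.72
DSVR,T10,30,30.36,101.2
DSVR,T11,50,50.01,100.01
DSVR,T12,20,20.12,100.61
DSVR,T13,60,59.67,99.44
DSVR,T14,60,59.64,99.4
DSVR,T15,50,49.64,99.28
DSVR,T16,60,59.36,98.93
OPLS-SVR,T1,20,19.77,98.87
OPLS-SVR,T2,20,20.13,100.63
OPLS-SVR,T3,30,30.21,100.7
OPLS-SVR,T4,30,30.21,100.7
OPLS-SVR,T5,60,59.79,99.65
OPLS-SVR,T6,30,30.15,100.51
OPLS-SVR,T7,20,19.83,99.17
OPLS-SVR,T8,50,50.04,100.09
OPLS-SVR,T9,50,49.95,99.89
OPLS-SVR,T10,30,30.21,100.7
OPLS-SVR,T11,50,49.51,99.019
OPLS-SVR,T12,20,19.79,98.97
OPLS-SVR,T13,60,59.86,99.76
OPLS-SVR,T14,60,59.79,99.65
OPLS-SVR,T15,50,50.11,100.23
OPLS-SVR,T16,60,60.21,100.35
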