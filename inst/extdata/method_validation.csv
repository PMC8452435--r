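analyte,slope,intercept,r_squared,range_low,range_high,lod_ng,loq_ng,intraday_rsd_pct,interday_rsd_pct,repeat_mean_ug_g,repeat_rsd_pct,recovery_mean_pct,recovery_rsd_pct
G,6564.29,-354.886,0.9998,0.9868,98.68,0.3,0.9,2.73,4.08,152.1,0.91,101.9,2.10
A,9880.28,530.894,0.9991,1.1152,111.52,0.4,1.1,1.26,1.30,108.7,0.61,91.1,2.45
U,2565.74,890.19,0.9983,1.2,120,0.4,1.2,0.32,0.86,4.2,2.45,88.4,3.78
C,772.496,1260.27,0.996,5.742,574.2,1.9,5.7,0.47,1.91,36.9,1.41,97.0,1.76
I,11955,391.889,0.9989,0.9276,92.76,0.3,0.9,0.55,1.57,187.0,0.74,95.9,2.24
dG,4320.97,-506.873,0.9997,0.8768,87.68,0.3,0.9,0.78,2.14,9.6,1.42,90.9,2.60
dA,584.119,974.144,0.9918,5.752,575.2,1.9,5.7,1.41,3.12,13.5,2.38,89.0,2.81
dU,839.666,943.893,0.9965,4.58,458,1.5,4.5,2.80,3.22,44.9,0.99,104.7,2.01
dC,548.202,664.266,0.9930,4.402,440.2,1.5,4.5,0.58,2.37,6.6,2.47,89.9,2.52
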