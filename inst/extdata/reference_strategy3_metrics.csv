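run,pam_pct,ca_pct,se_pct,sp_pct,auc,j,fm
1,82.07,91.46,94.23,86.66,0.90,0.88,0.93
2,75.43,87.80,90.38,83.33,0.87,0.82,0.90
3,79.46,90.24,94.23,83.33,0.89,0.86,0.92
4,76.37,89.02,96.15,77.67,0.86,0.85,0.92
5,72.48,86.59,92.31,76.67,0.84,0.81,0.90
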