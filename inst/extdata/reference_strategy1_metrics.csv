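run,pam_pct,ca_pct,se_pct,sp_pct,auc,j,fm
1,53.04,74.81,72.97,77.05,0.75,0.61,0.76
2,53.04,74.81,72.97,77.05,0.75,0.61,0.76
3,52.19,74.07,77.03,70.49,0.74,0.62,0.77
4,52.28,74.07,79.73,67.21,0.73,0.63,0.77
5,54.51,75.56,82.43,67.21,0.75,0.65,0.79
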