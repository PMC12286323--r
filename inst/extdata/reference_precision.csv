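strategy,run,precision_pct
1,1,79.41
1,2,79.41
1,3,76.00
1,4,74.65
1,5,75.31
3,1,92.45
3,2,90.38
3,3,90.74
3,4,87.72
3,5,87.27
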