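run,tp,fn,tn,fp
1,49,3,26,4
2,47,5,25,5
3,49,3,25,5
4,50,2,23,7
5,48,4,23,7
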