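run,tp,fn,tn,fp
1,54,20,47,14
2,54,20,47,14
3,57,17,43,18
4,59,15,41,20
5,61,13,41,20
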