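lipid,genotype,n,mean,sd
triglyceride,TT,1150,1.29,0.82
triglyceride,TC,953,1.46,0.86
triglyceride,CC,191,2.09,1.70
hdl_c,TT,1150,1.48,0.33
hdl_c,TC,953,1.44,0.32
hdl_c,CC,191,1.30,0.31
ldl_c,TT,1150,2.78,0.73
ldl_c,TC,953,2.87,0.77
ldl_c,CC,191,2.78,0.79
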