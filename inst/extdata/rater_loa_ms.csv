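pair,bias,loa_lower,loa_upper,max_precision
1 vs 2,2,-19.6,23.4,43.0
1 vs 3,3.2,-21.4,28.0,49.4
2 vs 3,5.2,-19.8,30.0,49.8
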