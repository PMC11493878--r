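parameter,hc_mean,hc_sd,hc_n,ci_mean,ci_sd,ci_n
moca,27.94,1.43,18,23.25,1.57,16
age,68.33,5.13,18,71.94,3.99,16
memory_t0,13.11,4.43,18,9.38,4.70,16
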