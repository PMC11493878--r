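group,male,female
HC,4,14
CI,10,6
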