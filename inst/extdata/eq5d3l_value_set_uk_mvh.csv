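dimension,level,decrement
constant,0,0.081
n3,0,0.269
mobility,2,0.069
mobility,3,0.314
self_care,2,0.104
self_care,3,0.214
usual,2,0.036
usual,3,0.094
pain,2,0.123
pain,3,0.386
anxiety,2,0.071
anxiety,3,0.236
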