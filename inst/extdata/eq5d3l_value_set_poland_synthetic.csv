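dimension,level,decrement
constant,0,0.075
n3,0,0.250
mobility,2,0.060
mobility,3,0.300
self_care,2,0.090
self_care,3,0.200
usual,2,0.040
usual,3,0.110
pain,2,0.100
pain,3,0.300
anxiety,2,0.070
anxiety,3,0.200
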