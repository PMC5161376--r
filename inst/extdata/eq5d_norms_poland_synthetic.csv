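age_low,age_high,sex,utility
18,25,male,0.960
18,25,female,0.950
25,35,male,0.945
25,35,female,0.935
35,45,male,0.925
35,45,female,0.915
45,55,male,0.895
45,55,female,0.880
55,65,male,0.860
55,65,female,0.840
65,75,male,0.825
65,75,female,0.800
75,110,male,0.780
75,110,female,0.750
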