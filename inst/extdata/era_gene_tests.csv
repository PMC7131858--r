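age_band,low_risk,intermediate_risk,high_risk,brca_carriers,total
<25,44,23,8,36,111
25-29,23,19,24,35,101
30-34,44,24,58,49,175
35-39,68,38,115,62,283
40-44,64,44,115,80,303
45-49,83,45,123,66,317
50-54,74,24,132,58,288
55-59,57,15,107,38,217
60-64,41,14,92,37,184
65-69,40,3,82,35,160
70-74,51,3,101,48,203
Total,589,252,957,544,2342
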