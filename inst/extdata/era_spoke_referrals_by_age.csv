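count,age_band,percent
8518,45-49,38.2
3836,50-54,17.2
2856,55-59,12.8
2511,60-64,11.3
2354,65-69,10.6
2214,70-74,9.9
22289,All,100
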