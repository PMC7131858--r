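age_band,gp,specialist,screening_program,total,percent,refused,low_risk,intermediate_risk,high_risk
<35,560,840,0,1400,12,32,237,424,707
35-39,403,722,0,1125,9.6,26,191,365,543
40-44,509,887,49,1445,12.4,35,309,453,648
45-49,246,432,1832,2510,21.5,96,835,663,916
50-54,214,369,1153,1736,14.9,48,612,423,653
55-59,140,234,861,1235,10.6,28,458,260,489
60-64,100,146,743,989,8.5,26,409,234,320
65-69,65,102,599,766,6.6,30,339,180,217
70-74,21,62,378,461,4,9,210,108,134
Total,2258,3794,5615,11667,100,330,3600,3110,4627
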