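source,lt35_assessed,lt35_hub,lt35_percent,a35_44_assessed,a35_44_hub,a35_44_percent,a45_74_assessed,a45_74_hub,a45_74_percent,total_assessed,total_hub,total_percent
gp,556,289,52.0,909,473,52.0,776,443,57.1,2241,1205,53.8
specialist,812,418,51.5,1552,699,45.0,1320,651,49.3,3684,1768,48.0
screening_program,0,0,0,48,19,39.6,5364,1635,30.5,5412,1654,30.6
Total,1368,717,52.4,2509,1191,47.5,7460,2729,36.6,11337,4627,40.8
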