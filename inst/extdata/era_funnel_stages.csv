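stage,count
screening_questionnaires,660040
spoke_invited_rbcsp,22289
spoke_phoned_rbcsp,5615
referred_gp,2258
referred_specialist,3794
spoke_arrived,11667
spoke_evaluated,11337
high_risk,4627
hub_from_spoke,2815
hub_direct,2739
hub_evaluated,5554
test_performed,2342
brca_carriers,544
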