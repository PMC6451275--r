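expert_id,round,perinatal_reduction_pct,maternal_reduction_pct
E1,1,20,45
E2,1,15,6
E3,1,30,5
E4,1,35,20
E5,1,45,40
E6,1,55,15
E7,1,70,60
E8,1,65,65
E1,2,10,50
E2,2,15,6
E3,2,25,2
E4,2,40,12
E5,2,45,40
E6,2,50,8
E7,2,60,55
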