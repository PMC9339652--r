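subject_id,visit_index,months_since_baseline,age_years,sex,education_years,diagnosis,cdr_global,lm_immediate,lm_delayed,trails_a_seconds,trails_b_seconds,animals,vegetables
S001,0,0,72.4,FEMALE,16,NORMAL,0,10,9,30,80,21,15
S001,1,12.5,73.4,FEMALE,16,NORMAL,0,10,9,25,78,20,14
S001,2,24.1,74.4,FEMALE,16,NORMAL,0,11,10,28,82,19,15
S002,0,0,68.9,MALE,12,MCI,0.5,7,5,48,140,14,9
S002,1,11.8,69.9,MALE,12,MCI,0.5,6,,55,150,12,8
S002,2,23.6,70.9,MALE,12,DEMENTIA,1,,,,,,
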