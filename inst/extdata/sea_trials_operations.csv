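codend,haul_id,date,n_cover,n_codend,q_cover,q_codend,duration_min,max_depth_m,speed_kt
shaking,1,2019-07-16,337,390,0.2643,0.0845,18,129,2.4
shaking,2,2019-07-16,371,199,0.8690,0.2701,10,129,2.5
shaking,3,2019-07-16,363,163,0.1974,0.0838,6,132,2.5
shaking,4,2019-07-16,369,285,0.6452,0.3432,6,140,2.4
T90,5,2019-07-17,81,287,1,0.6435,5,179,2.4
T90,6,2019-07-17,156,133,1,0.2036,9,180,2.3
T90,7,2019-07-17,319,349,0.3734,0.0957,10,178,2.6
T90,8,2019-07-17,358,358,0.1533,0.0567,9,177,2.5
T90,9,2019-07-17,337,234,1,0.0871,7,178,2.5
T90,10,2019-07-17,65,138,1,0.2108,7,176,2.5
T90,11,2019-07-18,384,384,0.6540,0.1115,7,172,2.4
T90,12,2019-07-18,407,362,0.4815,0.0975,8,172,2.4
T90,13,2019-07-18,339,334,0.2018,0.0839,6,178,2.5
T90,14,2019-07-18,328,364,0.3385,0.0707,5,177,2.6
T90,15,2019-07-18,305,335,0.1860,0.0560,4,172,2.4
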