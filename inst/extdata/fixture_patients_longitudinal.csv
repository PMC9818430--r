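patient_id,t_weeks,ca125_iu_ml,cycles_completed,paracenteses_cum
A,0,3328,0,0
A,3,830,1,0
A,6,121,2,0
A,9,37,3,0
A,12,19,4,0
A,15,16,5,0
B,0,748,0,0
B,3,706,1,1
B,6,649,2,2
C,0,679,0,0
C,9,91,3,0
C,14,48,4,0
C,17,44,5,0
D,0,5192,0,0
D,3,2057,1,0
D,6,344,2,1
D,9,93,3,1
D,12,37,4,1
D,17,19,5,1
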