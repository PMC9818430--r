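patient_id,ps,pc_epigastric,ascites,n_cycles_total,n_paracenteses_total,decision_time_weeks,resectable
A,1,0,1,6,0,18,1
B,0,1,1,4,2,9,0
C,1,1,1,6,0,20,1
D,1,1,1,6,1,20,0
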