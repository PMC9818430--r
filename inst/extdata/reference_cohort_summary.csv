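variable,level,n_not_resectable,n_resectable
ca125_lt75_after_cycle3,yes,13,33
ca125_lt75_after_cycle3,no,24,7
pc_hepatic_hilum_or_stomach,yes,20,10
pc_hepatic_hilum_or_stomach,no,17,30
resectable_total,,37,40
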