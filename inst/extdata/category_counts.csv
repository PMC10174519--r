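analysis,A,B,C,D,E,F
three_lab_adjusted_0.05,35,11,7,12,47,40
impc_adjusted_0.05,29,1,3,14,16,29
treatment_effect_in_genotypes,1,1,2,1,2,11
treatment_contrast_between_genotypes,0,1,8,0,1,35
naive_threshold_0.005,38,8,7,24,35,40
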