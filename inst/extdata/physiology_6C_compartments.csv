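"compartment","volume_mL","flow_mL_per_s","f_lipid","f_water"
"arterial",0.02,NA,0,1
"venous",0.05,NA,0,1
"brain",0.01,8e-05,0.08,0.78
"gonads",0.05,2e-05,0.15,0.75
"liver",0.01,8e-05,0.05,0.75
"other",0.51,0.00182,0.0223529411764706,0.797647058823529
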