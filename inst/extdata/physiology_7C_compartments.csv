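"compartment","volume_mL","flow_mL_per_s","f_lipid","f_water"
"arterial",0.02,NA,0,1
"venous",0.05,NA,0,1
"brain",0.01,8e-05,0.08,0.78
"gonads",0.05,2e-05,0.15,0.75
"liver",0.01,8e-05,0.05,0.75
"ppt",0.45,0.00132,0.02,0.8
"rpt",0.06,5e-04,0.04,0.78
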