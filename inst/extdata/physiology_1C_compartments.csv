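"compartment","volume_mL","flow_mL_per_s","f_lipid","f_water"
"body",0.65,NA,0.0310769230769231,0.814769230769231
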