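"body_mass_g","Qc","Qw","assimilation_factor"
0.65,NA,0.008,NA
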