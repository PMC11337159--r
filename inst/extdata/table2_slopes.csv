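protein,repeats,spin_slope_nm_per_uM,spin_slope_err,drop_slope_nm_per_uM,drop_slope_err
CTPR4,4,0.054,0.005,0.50,0.03
CTPR8,8,0.075,0.004,1.2,0.1
CTPR16,16,0.23,0.03,3.0,0.3
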