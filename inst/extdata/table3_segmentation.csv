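cluster,area_mm2,thickness_nm,volume_1e3_um3
b,2.0,17,34
c,0.9,96,84
d,0.5,151,72
total,3.4,NA,191
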