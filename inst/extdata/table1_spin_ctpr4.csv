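concentration_uM,concentration_err_uM,microreflectance_nm,microreflectance_err_nm,ellipsometry_nm,ellipsometry_err_nm,afm_nm,afm_err_nm
100,3,3,2,5,1,3,1
200,6,12,2,12,1,12,1
300,8,16,2,18,1,17,1
400,10,21,2,23,1,21,1
500,10,25,2,28,1,24,2
600,20,33,2,32,1,31,2
700,20,36,2,36,1,34,2
800,20,42,2,41,1,41,2
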