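wavelength_nm,n,k
380,6.03,0.72
390,5.79937,0.53962
400,5.57,0.387
410,5.33375,0.31544
420,5.12,0.276
430,4.96562,0.23669
440,4.84,0.2
450,4.72188,0.15206
460,4.62,0.11
470,4.5425,0.09212
480,4.47,0.081
490,4.37625,0.06162
500,4.29,0.045
510,4.23875,0.03975
520,4.2,0.038
530,4.15875,0.03375
540,4.12,0.03
550,4.08375,0.02825
560,4.05,0.027
570,4.01875,0.025
580,3.99,0.023
590,3.96375,0.02144
600,3.94,0.02
610,3.91937,0.01844
620,3.9,0.017
630,3.87938,0.01594
640,3.86,0.015
650,3.84438,0.014
660,3.83,0.013
670,3.815,0.01194
680,3.8,0.011
690,3.78437,0.01045
700,3.77,0.01
710,3.75824,0.00942
720,3.74772,0.00879
730,3.73808,0.00815
740,3.72896,0.00754
750,3.72,0.007
760,3.71136,0.00654
770,3.70328,0.00613
780,3.69552,0.00575
790,3.68784,0.00538
800,3.68,0.005
810,3.67184,0.00458
820,3.66352,0.00415
830,3.65528,0.00373
840,3.64736,0.00334
850,3.64,0.003
860,3.6332,0.00274
870,3.6268,0.00253
880,3.6208,0.00235
890,3.6152,0.00218
900,3.61,0.002
910,3.60536,0.00179
920,3.60128,0.00158
930,3.59752,0.00136
940,3.59384,0.00117
950,3.59,0.001
960,3.586,0.00087
970,3.582,0.00076
980,3.578,0.00068
990,3.574,0.00059
1000,3.57,5e-04
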