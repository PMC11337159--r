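wavelength_nm,n,k
380,1.47248,0
390,1.47125,0
400,1.47012,0
410,1.46907,0
420,1.46809,0
430,1.46719,0
440,1.46635,0
450,1.46557,0
460,1.46483,0
470,1.46415,0
480,1.4635,0
490,1.4629,0
500,1.46233,0
510,1.46179,0
520,1.46128,0
530,1.4608,0
540,1.46034,0
550,1.45991,0
560,1.4595,0
570,1.45911,0
580,1.45873,0
590,1.45838,0
600,1.45804,0
610,1.45771,0
620,1.4574,0
630,1.4571,0
640,1.45681,0
650,1.45653,0
660,1.45627,0
670,1.45601,0
680,1.45576,0
690,1.45552,0
700,1.45529,0
710,1.45507,0
720,1.45485,0
730,1.45464,0
740,1.45444,0
750,1.45424,0
760,1.45404,0
770,1.45385,0
780,1.45367,0
790,1.45349,0
800,1.45332,0
810,1.45315,0
820,1.45298,0
830,1.45282,0
840,1.45266,0
850,1.4525,0
860,1.45234,0
870,1.45219,0
880,1.45204,0
890,1.4519,0
900,1.45175,0
910,1.45161,0
920,1.45147,0
930,1.45134,0
940,1.4512,0
950,1.45107,0
960,1.45093,0
970,1.4508,0
980,1.45067,0
990,1.45054,0
1000,1.45042,0
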