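"wavelength_nm","L","M","S","rod","ipRGC"
380,0.00026459,6.045e-05,0.00679841,0.00058966,0.00050359
385,0.00048326,0.00011609,0.01236674,0.00110975,0.0009758
390,0.00103812,0.00028091,0.02747458,0.00221147,0.00201918
395,0.00206035,0.00063666,0.05626808,0.0045347,0.0043234
400,0.00354348,0.00115684,0.09770614,0.0093004,0.00927279
405,0.00561868,0.00192321,0.1559349,0.01854062,0.01928154
410,0.00910522,0.00355881,0.26103663,0.03487898,0.03762575
415,0.01451595,0.00657644,0.43130128,0.0604693,0.0672024
420,0.02044994,0.01050658,0.61191347,0.09670809,0.10998279
425,0.02544765,0.01492684,0.74639792,0.14371775,0.16630642
430,0.02972918,0.02058549,0.84474511,0.20002357,0.23448323
435,0.03374015,0.02811834,0.92633159,0.26279634,0.31110122
440,0.03714883,0.03654038,0.98161236,0.32846713,0.39177311
445,0.03958515,0.04489302,1,0.39357721,0.47213536
450,0.04130308,0.05394388,0.99565867,0.45550913,0.5486906
455,0.04308908,0.06504975,0.9811463,0.51315437,0.61958099
460,0.04723557,0.08019772,0.93784406,0.56763446,0.68544015
465,0.05590703,0.1009137,0.84736687,0.62154166,0.74843841
470,0.0692503,0.12624859,0.72344118,0.67675642,0.8095712
475,0.08695824,0.15491702,0.58713688,0.73467247,0.8688694
480,0.10892549,0.18676374,0.45678602,0.79388734,0.92270571
485,0.13561642,0.22270042,0.34714104,0.85171629,0.96591801
490,0.16957245,0.26677642,0.26137375,0.90501155,0.99325895
495,0.21390763,0.32369324,0.19854143,0.95015072,1
500,0.27194944,0.39762321,0.15282386,0.98309883,0.98266057
505,0.3460707,0.49074012,0.11772024,1,0.94008773
510,0.43461233,0.59775295,0.08888505,0.99811561,0.87429902
515,0.53313778,0.7098462,0.06365456,0.97625497,0.79011158
520,0.63013243,0.81157139,0.04393686,0.93604624,0.69490002
525,0.7147912,0.88943541,0.03159127,0.88030793,0.59588039
530,0.78622504,0.94439939,0.02371017,0.81190749,0.49864608
535,0.84583381,0.98037519,0.01700189,0.73414496,0.407375
540,0.89425676,0.99862323,0.0114056,0.65072733,0.32497267
545,0.93218131,1,0.00746214,0.56536989,0.26298593
550,0.96124814,0.98639766,0.00488812,0.48153822,0.20548631
555,0.98280432,0.95950522,0.00323166,0.40210427,0.15591277
560,0.99606912,0.91916326,0.00219122,0.32916792,0.11494557
565,1,0.86518142,0.0015375,0.26414376,0.08249157
570,0.99463478,0.79909399,0.00117989,0.2078323,0.05779997
575,0.98015342,0.72293455,0.00104068,0.16037164,0.03969136
580,0.95622393,0.63900923,0.00095515,0.12133562,0.02682394
585,0.92277173,0.55013977,0.00078915,0.09001373,0.01791378
590,0.88126379,0.46093778,0.00061804,0.06557329,0.01186611
595,0.83324346,0.37604247,0.00052929,0.04699256,0.00782114
600,0.77901807,0.29841365,0.00044948,0.03318709,0.00514285
605,0.71890631,0.23034746,0.00030328,0.02313597,0.00338067
610,0.65450827,0.17316489,0.00016856,0.01594783,0.00222512
615,0.58719946,0.1274415,0.00012577,0.01088825,0.00146816
620,0.51617564,0.09174637,0.00011237,0.00737825,0.00097195
625,0.44156068,0.06428643,5.75e-05,0.00497256,0.00064601
630,0.36937088,0.0438266,0,0.00333873,0.00043127
635,0.3054433,0.02922197,0,0.00223709,0.00028929
640,0.24901252,0.01911721,0,0.00149868,0.00019501
645,0.19832769,0.01222491,3.12e-06,0.00100582,0.00013212
650,0.15432561,0.00768759,0,0.00067776,8.998e-05
655,0.11809913,0.00480004,0,0.00045937,6.16e-05
660,0.0886847,0.00302202,0,0.00031325,4.238e-05
665,0.0648962,0.00190694,2.2e-07,0.00021485,2.932e-05
670,0.04671551,0.00121385,0,0.00014817,2.038e-05
675,0.03399442,0.00077289,0,0.0001027,1.424e-05
680,0.02489687,0.00049182,0,7.158e-05,1e-05
685,0.01760181,0.00030623,2e-08,5.018e-05,7.06e-06
690,0.01203614,0.00018499,0,3.537e-05,5e-06
695,0.00837377,0.00010873,0,2.505e-05,3.57e-06
700,0.00602881,7.174e-05,0,1.782e-05,2.55e-06
705,0.00433689,6.506e-05,0,1.274e-05,1.84e-06
710,0.00307954,5.294e-05,0,9.15e-06,1.33e-06
715,0.00215675,8.63e-06,0,6.6e-06,9.6e-07
720,0.00149613,0,0,4.79e-06,7e-07
725,0.00103696,0,0,3.48e-06,5.1e-07
730,0.00073732,4.7e-06,0,2.55e-06,3.8e-07
735,0.00055307,4.726e-05,0,1.87e-06,2.8e-07
740,0.0004123,6.092e-05,0,1.38e-06,2.1e-07
745,0.00026191,2.479e-05,0,1.02e-06,1.5e-07
750,0.00015176,0,0,7.6e-07,1.1e-07
755,0.00012943,1.242e-05,0,5.7e-07,9e-08
760,0.00013027,3.414e-05,0,4.3e-07,6e-08
765,8.542e-05,4.97e-06,0,3.3e-07,5e-08
770,2.149e-05,0,0,2.5e-07,4e-08
775,1.011e-05,0,0,1.9e-07,3e-08
780,0,0,0,1.5e-07,2e-08
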