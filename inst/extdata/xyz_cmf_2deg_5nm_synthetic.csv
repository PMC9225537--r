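"wavelength_nm","xbar","ybar","zbar"
380,0.00273348,0.0002036,0.0113267
385,0.00496776,0.00037384,0.02060398
390,0.01094112,0.00081405,0.04577484
395,0.02220569,0.0016432,0.09374709
400,0.0384281,0.00284761,0.16278619
405,0.0611605,0.00454624,0.25979994
410,0.10138261,0.00752132,0.43490777
415,0.16561899,0.01230531,0.71858221
420,0.23314601,0.01776814,1.01949646
425,0.2825015,0.02275575,1.24355824
430,0.31651733,0.02768062,1.40741248
435,0.34180399,0.03307165,1.54334202
440,0.35579255,0.03835689,1.63544419
445,0.35545163,0.04294712,1.66607945
450,0.34507968,0.04728494,1.65884646
455,0.328616,0.05238553,1.63466769
460,0.30123358,0.06052257,1.56252272
465,0.25856433,0.07372087,1.41178053
470,0.20684198,0.09175111,1.20531048
475,0.15443301,0.11395371,0.97821669
480,0.10763316,0.14020189,0.7610418
485,0.07113595,0.17113357,0.57836455
490,0.04529689,0.20991256,0.43546943
495,0.02924249,0.2603249,0.3307858
500,0.02152146,0.32611952,0.25461669
505,0.02135848,0.40969064,0.19613127
510,0.03126012,0.50805067,0.14808956
515,0.05391129,0.61506817,0.10605355
520,0.08942856,0.71741816,0.0732023
525,0.1366115,0.80294621,0.05263357
530,0.19156003,0.87137377,0.03950303
535,0.25050888,0.92502918,0.0283265
540,0.31293182,0.9647925,0.01900264
545,0.3791337,0.99143631,0.01243252
550,0.44950462,1.00675161,0.00814399
555,0.52410975,1.01225604,0.0053842
560,0.60162928,1.00735548,0.00365075
565,0.68033023,0.99126435,0.0025616
570,0.75821194,0.96454317,0.00196579
575,0.83287468,0.92802444,0.00173386
580,0.90059016,0.88228239,0.00159135
585,0.95742633,0.82824845,0.00131479
590,0.99996468,0.76854101,0.0010297
595,1.02489396,0.70584076,0.00088184
600,1.02881817,0.64139069,0.00074887
605,1.00924328,0.57621048,0.00050528
610,0.96736798,0.51186416,0.00028083
615,0.90497147,0.44950117,0.00020954
620,0.82246244,0.38806824,0.00018722
625,0.72242596,0.32702629,9.58e-05
630,0.61752332,0.27009574,0
635,0.51997544,0.22090482,0
640,0.43016327,0.17845336,0
645,0.34659551,0.14108501,5.2e-06
650,0.27212227,0.10914742,0
655,0.20968323,0.08314887,0
660,0.15823238,0.06223645,0
665,0.1161933,0.04543629,3.7e-07
670,0.08385275,0.03265197,0
675,0.06116556,0.02372205,0
680,0.04489514,0.01734773,0
685,0.03179549,0.0122502,3e-08
690,0.02177423,0.0083682,0
695,0.01517529,0.00581496,0
700,0.01093435,0.00418429,0
705,0.00784786,0.00301469,0
710,0.00556365,0.00214303,0
715,0.00393428,0.00149095,0
720,0.00273716,0.00103218,0
725,0.00189711,0.0007154,0
730,0.00134267,0.00051032,0
735,0.00094903,0.00039803,0
740,0.00067334,0.00030567,0
745,0.00044621,0.00018933,0
750,0.00027765,0.0001047,0
755,0.0002203,9.362e-05,0
760,0.00019296,0.00010176,0
765,0.00014969,6.066e-05,0
770,3.932e-05,1.483e-05,0
775,1.85e-05,6.98e-06,0
780,0,0,0
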