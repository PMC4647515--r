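trial,domain,or,or_lcl,or_ucl,or_p,md,md_lcl,md_ucl,md_p
TOPICAL,QL,0.99840,0.92173,1.08145,0.4687,0.6433,-1.4409,2.7274,0.5450
TOPICAL,PF,1.10396,1.01803,1.19714,0.0168,3.2075,1.2060,5.2090,0.0017
TOPICAL,SF,1.00312,0.90378,1.11339,0.4932,0.9528,-2.0474,3.9529,0.5334
TOPICAL,RF,1.07206,0.96858,1.18660,0.1790,2.2751,-0.8554,5.4055,0.1542
TOPICAL,EF,1.13356,1.02036,1.25931,0.0196,2.3352,-0.2060,4.8763,0.0717
TOPICAL,CF,1.14062,1.03104,1.26184,0.0107,3.6824,1.5497,5.8152,0.0007
TOPICAL,FA,0.97062,0.88076,1.06965,0.5472,0.4928,-2.0393,3.0249,0.7027
TOPICAL,NV,1.03299,0.90587,1.17796,0.6279,2.0823,0.2119,3.9527,0.0291
TOPICAL,PA,0.84858,0.75492,0.95386,0.0060,-4.1552,-6.7318,-1.5786,0.0016
TOPICAL,DY,0.90265,0.83349,0.97755,0.0118,-6.9802,-9.8067,-4.1538,<.0001
TOPICAL,SL,1.06142,0.96736,1.16463,0.2078,-0.5849,-3.4526,2.2829,0.6892
TOPICAL,AP,1.14413,1.04285,1.25524,0.0044,7.7375,4.3808,11.0943,<.0001
TOPICAL,CO,0.94016,0.85740,1.03090,0.1892,-9.3181,-11.9276,-6.7085,<.0001
TOPICAL,DI,1.11676,0.99977,1.24744,0.0505,15.0773,12.5221,17.6324,<.0001
TOPICAL,FI,1.06304,0.94126,1.20057,0.3245,-3.9678,-5.8688,-2.0668,<.0001
SOCCAR,QL,1.05911,0.94600,1.18576,0.3186,-0.3363,-3.2927,2.6201,0.8234
SOCCAR,PF,1.00632,0.88085,1.14967,0.5260,-0.7855,-3.5393,1.9684,0.5758
SOCCAR,SF,1.07805,0.94331,1.23204,0.2696,-0.1569,-3.8385,3.5246,0.9333
SOCCAR,RF,0.92530,0.81065,1.05617,0.2497,-1.2639,-5.1956,2.6679,0.5283
SOCCAR,EF,0.86964,0.74753,1.01171,0.0704,-0.4552,-3.7208,2.8104,0.7845
SOCCAR,CF,1.21469,1.04469,1.41237,0.0115,2.8249,0.2230,5.4268,0.0334
SOCCAR,FA,1.09003,0.96258,1.23436,0.1740,-3.2001,-6.5586,0.1585,0.0618
SOCCAR,NV,0.96687,0.81577,1.14595,0.4073,1.1136,-1.6169,3.8441,0.4237
SOCCAR,PA,0.93405,0.81386,1.07199,0.3313,-3.3510,-6.7785,0.07654,0.0553
SOCCAR,DY,0.90277,0.81740,0.99707,0.0436,-2.0557,-5.5569,1.4456,0.2495
SOCCAR,SL,1.07573,0.95694,1.20927,0.2211,-0.8873,-4.4778,2.7033,0.6278
SOCCAR,AP,0.94817,0.83543,1.07613,0.4095,-0.2265,-4.0527,3.5997,0.9075
SOCCAR,CO,1.10100,0.95927,1.26368,0.1709,-0.8742,-4.4752,2.7267,0.6339
SOCCAR,DI,0.84506,0.68652,1.04021,0.1121,-0.4002,-2.8583,2.0580,0.7494
SOCCAR,FI,1.10633,0.94859,1.29029,0.1977,1.1951,-2.1001,4.4903,0.4768
Study 10,QL,0.94126,0.84476,1.05135,0.3912,-1.6241,-4.1816,1.8922,0.6124
Study 10,PF,1.00563,0.89071,1.13537,0.9276,2.8207,-1.9594,7.6007,0.2467
Study 10,SF,1.00006,0.88002,1.13647,0.9993,4.0507,-0.9736,9.0750,0.1139
Study 10,RF,1.28860,1.08877,1.50121,0.0084,13.0540,0.3211,25.7870,0.0445
Study 10,EF,1.07878,0.93850,1.24003,0.2156,-2.8502,-7.4563,1.7558,0.2248
Study 10,CF,1.14441,0.96173,1.29133,0.1494,5.6888,2.0359,9.3417,0.0023
Study 10,FA,0.87034,0.77408,0.97858,0.0203,-2.0359,-6.1599,2.0882,0.3327
Study 10,NV,1.10180,0.94137,1.28957,0.2269,0.7394,-2.9807,4.4594,0.6965
Study 10,PA,0.81452,0.70091,0.94655,0.0075,-0.9057,-5.0882,3.2768,0.6708
Study 10,DY,0.90282,0.82439,0.98871,0.0275,-6.8389,-11.3035,-2.3743,0.0027
Study 10,SL,0.95514,0.85447,1.06767,0.4188,-0.3213,-5.8080,5.1655,0.9085
Study 10,AP,1.08583,0.95447,1.23526,0.2104,2.2718,-2.6561,7.1997,0.3657
Study 10,CO,0.86569,0.75412,0.99376,0.0405,-2.6788,-7.7010,2.3433,0.2953
Study 10,DI,0.92437,0.77487,1.10271,0.3818,-3.4211,-6.4418,-0.4004,0.0265
Study 10,FI,1.06566,0.82875,1.27688,0.3624,2.1354,-2.1141,6.5714,0.3252
Study 11,QL,0.95236,0.89286,1.09135,0.5552,-2.3613,-5.1511,2.9822,0.7334
Study 11,PF,0.93089,0.84991,1.01958,0.1229,-2.7725,-6.0805,0.5356,0.1003
Study 11,SF,0.96121,0.87398,1.05714,0.4147,-3.3172,-6.9318,0.2974,0.0720
Study 11,RF,1.08853,0.94125,1.23477,0.3324,-7.1287,-14.3603,0.1028,0.0533
Study 11,EF,0.97549,0.88043,1.08081,0.6350,-4.8538,-8.0029,-1.7047,0.0026
Study 11,CF,0.95256,0.85588,1.06016,0.3731,-0.6141,-3.1705,1.9422,0.6374
Study 11,FA,1.10834,1.00731,1.21950,0.0349,3.3375,0.2209,6.4541,0.0359
Study 11,NV,1.29384,1.15215,1.42351,<0.0001,5.4863,3.3832,7.5895,<.0001
Study 11,PA,1.00011,0.89283,1.12028,0.9985,0.9084,-1.9043,3.7210,0.5264
Study 11,DY,1.04262,0.96229,1.12965,0.3073,-1.6110,-5.1973,1.9754,0.3783
Study 11,SL,1.02938,0.94433,1.12209,0.5102,-4.0055,-7.6480,-0.3629,0.0312
Study 11,AP,1.04393,0.94403,1.15440,0.4019,4.6020,0.7884,8.4157,0.0181
Study 11,CO,1.06104,0.95671,1.17675,0.1117,2.6096,-0.7817,6.0008,0.1314
Study 11,DI,1.13002,0.95487,1.33729,0.1547,0.9181,-0.9858,2.8219,0.3442
Study 11,FI,1.08816,0.92995,1.22408,0.4498,1.9684,-2.0451,5.6714,0.5022
Study 12,QL,0.96311,0.89103,1.04421,0.5034,-0.8545,-2.8925,1.19985,0.3214
Study 12,PF,1.00156,0.93624,1.07143,0.9639,-0.01443,-2.9124,2.8835,0.9922
Study 12,SF,0.93058,0.87602,0.98855,0.0196,0.2535,-2.2932,2.8002,0.8453
Study 12,RF,0.94478,0.89925,0.99755,0.0536,-6.3209,-11.8670,-0.7747,0.0255
Study 12,EF,0.96366,0.90173,1.02985,0.2747,-4.0689,-6.3917,-1.7461,0.0006
Study 12,CF,0.96082,0.89968,1.02612,0.1334,-1.2498,-3.1386,0.6391,0.1946
Study 12,FA,0.99963,0.94240,1.06033,0.4901,-0.6901,-2.8719,1.4917,0.5352
Study 12,NV,0.95818,0.88480,1.03765,0.2933,5.4863,3.3832,7.5895,<.0001
Study 12,PA,0.96961,0.89701,1.04809,0.4370,0.9084,-1.9043,3.7210,0.5264
Study 12,DY,1.03922,0.98989,1.09102,0.1210,3.9991,1.3876,6.6105,0.0027
Study 12,SL,0.90162,0.84630,0.96055,0.0014,-15.5470,-18.0563,-13.0378,<.0001
Study 12,AP,1.06787,0.99510,1.14597,0.0682,-2.2811,-4.6592,0.09705,0.0601
Study 12,CO,1.16848,1.09944,1.24186,<.0001,2.6096,-0.7817,6.0008,0.1314
Study 12,DI,1.05255,0.95709,1.15754,0.2909,-2.3379,-3.8004,-0.8754,0.0017
Study 12,FI,1.01842,0.92606,1.12000,0.7064,1.6197,-2.5375,5.7768,0.4445
Study 14,QL,0.96684,0.91236,1.05549,0.2123,-1.3897,-3.2450,0.9808,0.0983
Study 14,PF,0.95134,0.89346,1.01298,0.1193,-1.7843,-3.6934,0.1248,0.0670
Study 14,SF,1.01050,0.94612,1.07926,0.7557,0.8731,-1.1044,2.8507,0.3867
Study 14,RF,0.92540,0.89452,0.99358,0.0412,-6.0800,-10.1493,-2.0107,0.0034
Study 14,EF,0.89881,0.83696,0.96523,0.0034,-1.9677,-3.5103,-0.4251,0.0124
Study 14,CF,1.04520,0.96868,1.12776,0.2543,-0.07931,-1.4565,1.2978,0.9101
Study 14,FA,1.03864,0.97432,1.10720,0.2450,1.1338,-0.5280,2.7955,0.1811
Study 14,NV,0.92440,0.84363,1.01291,0.0920,-1.7769,-3.0100,-0.5437,0.0048
Study 14,PA,1.07278,0.98702,1.16600,0.0984,-0.5521,-2.2252,1.1210,0.5176
Study 14,DY,1.02074,0.96756,1.07683,0.4520,1.3292,-0.5879,3.2464,0.1741
Study 14,SL,0.96340,0.89862,1.03286,0.2937,-8.0830,-10.1365,-6.0295,<.0001
Study 14,AP,0.98802,0.91442,1.06755,0.7602,-3.8491,-5.8767,-1.8216,0.0002
Study 14,CO,1.07744,1.00746,1.15228,0.0295,10.9195,8.8799,12.9590,<.0001
Study 14,DI,1.05388,0.95077,1.16817,0.3177,-1.6529,-2.8431,-0.4628,0.0065
Study 14,FI,0.99605,0.89553,1.10785,0.9418,2.3020,-2.4081,7.0122,0.3375
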