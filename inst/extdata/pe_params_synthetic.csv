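station,latitude,PmB,alphaB
st001,62.98,1.236,0.07643
st002,69.63,3.2414,0.01799
st003,79.74,4.2805,0.02723
st004,62.79,1.2949,0.03384
st005,71.13,0.6083,0.04707
st006,69.5,1.2822,0.01602
st007,63.07,1.8131,0.09863
st008,76.54,1.9757,0.04111
st009,62.47,0.4221,0.04389
st010,65.97,1.817,0.01449
st011,73.95,2.7572,0.05955
st012,73.74,0.6773,0.05647
st013,74.06,2.5217,0.03624
st014,76.59,0.6504,0.07092
st015,57.34,1.7657,0.03323
st016,79.17,1.5028,0.08415
st017,78.6,2.1095,0.03986
st018,66.77,3.6757,0.04918
st019,62.84,1.5917,0.03934
st020,78.74,1.0709,0.03498
st021,73.13,1.0464,0.01018
st022,73.21,2.3364,0.01052
st023,76.39,1.1876,0.01906
st024,55.61,0.884,0.04629
st025,79.59,1.2825,0.0388
st026,52.7,0.8452,0.02132
st027,67.77,1.2315,0.02411
st028,61.41,2.9674,0.16741
st029,77.19,1.7339,0.01685
st030,52.87,1.2104,0.06032
st031,74.23,0.6619,0.02993
st032,57.01,4.5721,0.03187
st033,71,1.6195,0.04036
st034,71.06,2.6096,0.01836
st035,58.81,3.6964,0.00956
st036,62.01,2.6039,0.01521
st037,63.67,0.7847,0.02251
st038,64.04,0.5654,0.03799
st039,57.18,1.1909,0.03854
st040,72.4,2.4364,0.04244
st041,68.28,3.4619,0.00603
st042,75.85,0.9124,0.03492
st043,64.05,1.6895,0.0102
st044,72.89,1.7917,0.0335
st045,64.66,0.5664,0.07786
st046,77.56,2.2933,0.01475
st047,75.79,1.4813,0.04249
st048,77.2,1.3086,0.02947
st049,60.54,1.5312,0.03567
st050,67.68,3.622,0.05218
st051,65.52,1.4781,0.0157
st052,56.98,0.7484,0.02837
st053,74.91,3.4139,0.02448
st054,72.39,2.3507,0.02643
st055,71.94,0.5958,0.00986
st056,74.79,0.6391,0.03027
st057,70.81,2.2044,0.01201
st058,75.75,1.1915,0.02345
st059,69.21,1.2064,0.01917
st060,69.42,1.1812,0.02045
st061,67.33,0.722,0.02284
st062,70.8,1.3422,0.04781
st063,71.51,1.4773,0.02936
st064,69.39,0.5555,0.03615
st065,68.71,1.4088,0.02047
st066,76.38,0.7855,0.02591
st067,64.29,2.3661,0.02516
st068,73.19,0.8927,0.08453
st069,59.07,1.8566,0.02515
st070,69.1,1.8033,0.02756
st071,61.63,0.5522,0.06832
st072,57.98,1.3166,0.04326
st073,75.39,0.7335,0.02434
st074,68.65,4.5954,0.00835
st075,75.58,1.4462,0.07678
st076,78.33,1.9437,0.05788
st077,70.16,1.4428,0.01391
st078,69.65,0.6212,0.04618
st079,71.28,0.7811,0.01978
st080,62,0.4066,0.01746
st081,71.23,1.9646,0.08617
st082,73.9,2.0112,0.04362
st083,73.17,0.9959,0.02012
st084,75.09,0.9266,0.02117
st085,74.81,2.2117,0.01846
st086,60.89,2.1634,0.02365
st087,68.65,0.5644,0.0421
st088,62.63,5.1752,0.05203
st089,65.37,1.1051,0.02462
st090,70.26,0.6573,0.01422
st091,68.24,1.4128,0.09627
st092,77.07,2.0006,0.04383
st093,63,0.5149,0.04368
st094,64.12,2.2875,0.01938
st095,63.72,0.6117,0.03138
st096,64.28,3.5274,0.02082
st097,63.21,0.6103,0.02347
st098,65.83,1.2596,0.03635
st099,69.55,1.4679,0.01684
st100,76.65,1.2001,0.04348
st101,68.2,2.5196,0.0257
st102,63.52,1.234,0.09406
st103,71.79,1.1565,0.04108
st104,68.36,0.7528,0.01466
st105,71.23,1.9063,0.01587
st106,62.73,0.2676,0.03068
st107,61.06,6.3893,0.01123
st108,63.88,1.865,0.02748
st109,76.06,1.6265,0.03512
st110,75.35,1.2897,0.02698
st111,76.49,2.9581,0.05473
st112,56.3,1.3558,0.01014
st113,71.89,2.5846,0.01956
st114,73.7,1.381,0.01401
st115,54.18,2.1349,0.01679
st116,67.96,4.1869,0.03139
st117,72.76,1.8749,0.02611
st118,75.15,0.7179,0.04319
st119,63.41,2.2347,0.02995
st120,73.06,3.875,0.01717
st121,62.39,1.692,0.02812
st122,72.91,1.2164,0.02995
st123,68.32,1.3138,0.01806
st124,63.8,0.6555,0.02315
st125,63.65,1.5381,0.02037
st126,71.98,1.5682,0.0414
st127,77.67,2.6467,0.07672
st128,72.23,0.9523,0.01901
st129,71.69,1.6181,0.06537
st130,66.25,1.3404,0.03984
st131,65.45,0.3403,0.00967
st132,62.13,0.7616,0.03875
st133,67.8,1.9971,0.01636
st134,71.28,0.9562,0.02484
st135,66.3,1.1562,0.01711
st136,58.23,0.5353,0.07624
st137,61.99,2.1888,0.05616
st138,72.98,5.804,0.02483
st139,56.28,3.8628,0.03635
st140,78.88,1.1469,0.01352
st141,67.03,1.5546,0.0187
st142,76.39,1.6676,0.03629
st143,61.77,4.6048,0.04255
st144,73.06,0.5331,0.01713
st145,71.41,1.712,0.00855
st146,75.04,1.9356,0.01875
st147,60.55,3.7586,0.03293
st148,62.78,2.5178,0.03754
st149,61.78,1.2775,0.01098
st150,74.25,0.4882,0.06787
st151,68.23,0.9694,0.03637
st152,66.91,0.4824,0.03019
st153,76.11,0.36,0.03955
st154,75.97,1.1634,0.02982
st155,64.79,0.6794,0.01143
st156,72.54,1.532,0.02903
st157,52.54,0.3851,0.0255
st158,58.87,1.7496,0.0435
st159,68.25,1.3254,0.03569
st160,60.72,3.2778,0.0673
st161,76.4,0.8689,0.0158
st162,75.25,1.8949,0.01802
st163,78.68,5.8033,0.0285
st164,74.03,1.3312,0.06898
st165,54.55,2.48,0.05678
st166,68.42,3.5442,0.02494
st167,76.26,0.6678,0.02036
st168,54.75,4.452,0.02175
st169,69.99,1.7483,0.06768
st170,76.26,1.959,0.04367
st171,78.07,0.2755,0.04556
st172,58.35,1.3882,0.01188
st173,76.91,2.1804,0.0373
st174,65.82,2.1131,0.01132
st175,79.35,1.8122,0.07331
st176,64,1.9644,0.01466
st177,78.85,2.3691,0.02485
st178,69.22,0.7691,0.01353
st179,74.68,1.0597,0.02531
st180,61.44,4.8066,0.00687
st181,75.11,1.769,0.02901
st182,78.4,2.395,0.04839
st183,64.91,1.6414,0.02445
st184,75.87,0.9635,0.01665
st185,75.86,1.4561,0.03462
st186,65.91,1.4013,0.01413
st187,65.79,2.4211,0.03858
st188,74.12,1.7447,0.01939
st189,54.78,0.8096,0.04177
st190,60.75,1.5102,0.02527
st191,72.05,1.2938,0.02112
st192,63.15,1.8943,0.02022
st193,70.23,0.5059,0.02702
st194,56.97,1.7923,0.03673
st195,65.07,1.6054,0.01863
st196,58.83,1.7802,0.02922
st197,73.56,1.8099,0.03648
st198,71.88,1.1358,0.02019
st199,53.15,0.3495,0.01832
st200,62.25,0.591,0.02814
st201,67.89,0.7576,0.02198
st202,68.89,2.8059,0.01962
st203,79.36,4.0152,0.01763
st204,62,0.7465,0.0278
st205,70.72,2.0873,0.02163
st206,62.36,0.92,0.01531
st207,61.93,3.138,0.03444
st208,72.78,1.1928,0.01458
st209,73.3,1.2345,0.05001
st210,52.25,1.8311,0.07017
st211,70.54,3.0753,0.0164
st212,61.56,0.8576,0.14623
st213,73.5,1.1005,0.03552
st214,67.89,2.5505,0.04574
st215,65.04,0.8086,0.03315
st216,69.77,1.2409,0.03692
st217,75.56,0.955,0.04119
st218,77.78,1.5378,0.0166
st219,69.17,0.564,0.02448
st220,78.48,1.5181,0.01509
st221,79.34,3.0198,0.04587
st222,53.34,0.8807,0.06896
st223,69.1,2.5678,0.06995
st224,68.14,0.5364,0.01929
st225,73.08,0.7015,0.03775
st226,70.83,2.515,0.02426
st227,63.37,2.2448,0.02992
st228,69.06,1.2107,0.05391
st229,68.42,1.1879,0.01755
st230,75.81,1.2046,0.04762
st231,69.34,1.1959,0.02003
st232,77.24,1.1445,0.01272
st233,60.79,2.8226,0.04234
st234,63.76,0.6949,0.01785
st235,55.13,2.1763,0.02832
st236,79.45,0.6866,0.02077
st237,60.98,2.48,0.02497
st238,79.28,0.9501,0.03952
st239,73.45,0.5813,0.0358
st240,62.89,1.7952,0.01596
st241,73.67,1.6321,0.02428
st242,68.38,3.9044,0.02466
st243,65.77,0.7928,0.02222
st244,70.63,1.0005,0.0998
st245,54.76,2.1092,0.02651
st246,72.68,2.3474,0.08265
st247,78.13,1.8992,0.05268
st248,65.16,2.3619,0.01219
st249,62.21,2.8054,0.02112
st250,61.76,2.6936,0.01669
st251,79.11,0.7803,0.05203
st252,52.95,3.3711,0.01638
st253,62.38,2.6192,0.0153
st254,78.66,1.2337,0.04886
st255,77.54,1.9455,0.04989
st256,70.05,1.1406,0.02611
st257,72.79,2.0251,0.04783
st258,73.18,0.9879,0.04324
st259,78.86,0.6542,0.04023
st260,79.74,2.4175,0.03973
st261,68.48,0.7309,0.01843
st262,74.31,1.8696,0.02915
st263,61.9,0.4386,0.01227
st264,74.79,1.0804,0.0278
st265,54.07,1.8353,0.04544
st266,76.78,1.5825,0.0309
st267,67.38,3.32,0.0206
st268,76.67,1.8543,0.03541
st269,78.5,1.5896,0.02025
st270,77.89,0.9606,0.01313
st271,68.67,0.5536,0.02803
st272,70.52,3.9085,0.02176
st273,73.67,1.1317,0.06194
st274,74.06,0.6772,0.01778
st275,68.2,1.3698,0.06197
st276,75.22,0.6041,0.11081
st277,79.83,1.8521,0.05817
st278,56.93,2.7292,0.02383
st279,78.98,1.1349,0.01522
st280,68.62,3.4364,0.01378
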