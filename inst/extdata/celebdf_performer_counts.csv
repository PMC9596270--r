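performer,n_originals,n_donor_performers,n_fake_recordings,model,co,or_alone,fa_alone,pct_common,pct_original_alone,pct_fake_alone
0,10,13,114,dynamic,2608,2406,3026,52.01,47.99,60.35
1,10,17,153,dynamic,8943,8529,6405,51.18,48.82,36.66
2,10,17,158,dynamic,1652,1871,3866,46.89,53.11,109.74
3,10,17,157,dynamic,3868,6988,2691,35.63,64.37,24.79
4,10,15,140,dynamic,3939,4129,3001,48.82,51.18,37.2
5,10,3,18,dynamic,508,452,453,52.92,47.08,47.19
6,10,17,134,dynamic,3718,3055,3386,54.89,45.11,49.99
7,10,4,29,dynamic,1167,779,1170,59.97,40.03,60.12
8,10,9,33,dynamic,2990,2980,661,50.08,49.92,11.07
9,10,17,124,dynamic,5582,4460,2652,55.59,44.41,26.41
10,10,4,33,dynamic,3155,1101,1089,74.13,25.87,25.59
11,11,1,11,dynamic,877,356,238,71.13,28.87,19.3
12,7,2,11,dynamic,941,229,543,80.43,19.57,46.41
13,16,2,23,dynamic,2169,1263,465,63.2,36.8,13.55
16,14,16,203,dynamic,5853,8438,3792,40.96,59.04,26.53
17,10,16,143,dynamic,8448,4272,1773,66.42,33.58,13.94
19,10,9,72,dynamic,2342,951,1667,71.12,28.88,50.62
20,10,27,212,dynamic,7194,6925,3443,50.95,49.05,24.39
21,10,27,205,dynamic,1486,3504,2508,29.78,70.22,50.26
22,10,9,52,dynamic,96,139,615,40.85,59.15,261.7
23,10,27,218,dynamic,5353,5838,4246,47.83,52.17,37.94
24,10,9,79,dynamic,4402,2536,2280,63.45,36.55,32.86
25,11,9,59,dynamic,1584,1279,1067,55.33,44.67,37.27
26,10,27,170,dynamic,5075,5278,2501,49.02,50.98,24.16
27,10,9,77,dynamic,2147,2517,878,46.03,53.97,18.83
28,10,27,249,dynamic,3236,3125,5438,50.87,49.13,85.49
29,10,13,103,dynamic,2901,3679,1722,44.09,55.91,26.17
30,10,21,201,dynamic,2731,3096,7776,46.87,53.13,133.45
31,10,21,197,dynamic,1372,4774,3566,22.32,77.68,58.02
32,10,13,88,dynamic,1435,1081,2163,57.03,42.97,85.97
33,10,13,109,dynamic,4217,3536,4852,54.39,45.61,62.58
34,10,13,87,dynamic,4654,2113,3162,68.77,31.23,46.73
35,10,21,182,dynamic,4653,5571,5360,45.51,54.49,52.43
37,10,21,172,dynamic,3197,3374,5264,48.65,51.35,80.11
38,10,13,104,dynamic,3032,2957,790,50.63,49.37,13.19
39,10,8,72,dynamic,3694,1242,1620,74.84,25.16,32.82
40,10,9,83,dynamic,7527,2201,1783,77.37,22.63,18.33
41,10,8,71,dynamic,3497,2381,1616,59.49,40.51,27.49
42,5,9,36,dynamic,3505,968,1184,78.36,21.64,26.47
43,10,9,79,dynamic,5443,1088,3761,83.34,16.66,57.59
44,6,9,46,dynamic,1861,1435,1013,56.46,43.54,30.73
45,10,9,87,dynamic,3411,3814,2408,47.21,52.79,33.33
46,10,9,76,dynamic,1945,1702,1573,53.33,46.67,43.13
47,10,9,89,dynamic,3884,1660,2426,70.06,29.94,43.76
48,10,9,84,dynamic,5035,2619,2322,65.78,34.22,30.34
49,10,9,84,dynamic,2406,1865,3894,56.33,43.67,91.17
50,10,8,71,dynamic,3302,3216,4478,50.66,49.34,68.7
51,10,8,67,dynamic,11224,4040,1850,73.53,26.47,12.12
52,10,8,79,dynamic,8931,6069,2812,59.54,40.46,18.75
53,10,9,86,dynamic,9810,6115,2557,61.6,38.4,16.06
54,10,9,80,dynamic,11734,5870,3106,66.66,33.34,17.64
55,10,9,64,dynamic,7576,2783,4395,73.13,26.87,42.43
56,10,9,79,dynamic,9131,3168,3366,74.24,25.76,27.37
57,10,9,63,dynamic,4874,2652,3366,64.76,35.24,44.72
58,10,8,55,dynamic,4436,2726,3208,61.94,38.06,44.79
59,10,3,23,dynamic,1036,840,955,55.22,44.78,50.91
60,10,3,30,dynamic,1862,2647,1682,41.3,58.7,37.3
61,10,3,15,dynamic,360,483,907,42.7,57.3,107.59
0,10,13,114,static,5029,8427,7012,37.37,62.63,52.11
1,10,17,153,static,12674,11117,12469,53.27,46.73,52.41
2,10,17,158,static,5515,10780,8253,33.84,66.16,50.65
3,10,17,157,static,4409,4280,16585,50.74,49.26,190.87
4,10,15,140,static,11665,7909,11677,59.59,40.41,59.66
5,10,3,18,static,2323,1568,959,59.70,40.30,24.65
6,10,17,134,static,15487,8694,7760,64.05,35.95,32.09
7,10,4,29,static,3419,1811,2479,65.37,34.63,47.40
8,10,9,33,static,3486,4096,2626,45.98,54.02,34.63
9,10,17,124,static,8850,9186,3892,49.07,50.93,21.58
10,10,4,33,static,3376,2428,785,58.17,41.83,13.53
11,11,1,11,static,1686,926,719,64.55,35.45,27.53
12,7,2,11,static,1559,576,928,73.02,26.98,43.47
13,16,2,23,static,3422,2904,974,54.09,45.91,15.40
16,14,16,203,static,23137,19710,14574,54.00,46.00,34.01
17,10,16,143,static,10427,6117,5311,63.03,36.97,32.10
19,10,9,72,static,3234,3449,2858,48.39,51.61,42.77
20,10,27,212,static,33724,30693,8398,52.35,47.65,13.04
21,10,27,205,static,12585,10429,10840,54.68,45.32,47.10
22,10,9,52,static,4371,3393,1415,56.30,43.70,18.23
23,10,27,218,static,24505,16198,13878,60.20,39.80,34.10
24,10,9,79,static,6526,3265,5013,66.65,33.35,51.20
25,11,9,59,static,3596,5512,2352,39.48,60.52,25.82
26,10,27,170,static,6988,4953,11561,58.52,41.48,96.82
27,10,9,77,static,2951,1430,3247,67.36,32.64,74.12
28,10,27,249,static,15921,10156,13149,61.05,38.95,50.42
29,10,13,103,static,10211,10678,6299,48.88,51.12,30.15
30,10,21,201,static,40638,39511,9427,50.70,49.30,11.76
31,10,21,197,static,39716,30033,16023,56.94,43.06,22.97
32,10,13,88,static,16032,6920,5593,69.85,30.15,24.37
33,10,13,109,static,18643,15752,11702,54.20,45.80,34.02
34,10,13,87,static,7265,5690,5222,56.08,43.92,40.31
35,10,21,182,static,15156,14880,12323,50.46,49.54,41.03
37,10,21,172,static,32742,21484,16629,60.38,39.62,30.67
38,10,13,104,static,8002,5657,7295,58.58,41.42,53.41
39,10,8,72,static,10710,5169,5005,67.45,32.55,31.52
40,10,9,83,static,12327,4566,4189,72.97,27.03,24.80
41,10,8,71,static,9380,5408,4002,63.43,36.57,27.06
42,5,9,36,static,3994,1109,1095,78.27,21.73,21.46
43,10,9,79,static,9751,8985,4371,52.04,47.96,23.33
44,6,9,46,static,2820,2540,1139,52.61,47.39,21.25
45,10,9,87,static,4296,4011,3640,51.72,48.28,43.82
46,10,9,76,static,3233,3416,2993,48.62,51.38,45.01
47,10,9,89,static,14475,4996,6221,74.34,25.66,31.95
48,10,9,84,static,10434,5901,4678,63.88,36.12,28.64
49,10,9,84,static,9071,8312,5011,52.18,47.82,28.83
50,10,8,71,static,4821,2292,8265,67.78,32.22,116.20
51,10,8,67,static,17190,7082,4431,70.82,29.18,18.26
52,10,8,79,static,21332,14171,6285,60.09,39.91,17.70
53,10,9,86,static,17295,10690,3707,61.80,38.20,13.25
54,10,9,80,static,13703,6736,6694,67.04,32.96,32.75
55,10,9,64,static,10837,4537,5743,70.49,29.51,37.36
56,10,9,79,static,14968,7330,5804,67.13,32.87,26.03
57,10,9,63,static,6896,5005,3735,57.94,42.06,31.38
58,10,8,55,static,6122,4539,4179,57.42,42.58,39.20
59,10,3,23,static,3038,1975,2735,60.60,39.40,54.56
60,10,3,30,static,3853,4919,3415,43.92,56.08,38.93
61,10,3,15,static,1796,1459,1285,55.18,44.82,39.48
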