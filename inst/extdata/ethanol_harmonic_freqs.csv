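mode,trans_pes,trans_ab,gauche_pes,gauche_ab
1,243,222,268,258
2,273,274,278,271
3,417,413,424,420
4,818,813,804,803
5,909,907,894,895
6,1055,1049,1075,1069
7,1115,1115,1094,1096
8,1181,1180,1144,1141
9,1284,1274,1290,1284
10,1302,1300,1375,1374
11,1403,1402,1406,1402
12,1454,1456,1424,1426
13,1488,1484,1490,1491
14,1500,1501,1496,1497
15,1530,1531,1519,1522
16,2995,3001,3007,3014
17,3028,3036,3020,3028
18,3036,3042,3088,3089
19,3120,3122,3108,3108
20,3126,3127,3121,3123
21,3862,3853,3845,3837
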