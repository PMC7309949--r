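age,qx_male,qx_female
0,0.000212611,0.000104223
1,0.000213967,0.000104714
2,0.000215469,0.000105263
3,0.000217132,0.000105876
4,0.000218974,0.00010656
5,0.000221014,0.000107323
6,0.000223272,0.000108175
7,0.000225774,0.000109126
8,0.000228543,0.000110188
9,0.000231611,0.000111373
10,0.000235007,0.000112696
11,0.000238768,0.000114173
12,0.000242934,0.000115822
13,0.000247546,0.000117662
14,0.000252654,0.000119716
15,0.00025831,0.000122009
16,0.000264573,0.000124569
17,0.000271509,0.000127426
18,0.00027919,0.000130616
19,0.000287695,0.000134176
20,0.000297114,0.000138151
21,0.000307544,0.000142587
22,0.000319094,0.00014754
23,0.000331884,0.000153068
24,0.000346047,0.000159239
25,0.000361731,0.000166128
26,0.000379099,0.000173817
27,0.000398332,0.000182401
28,0.000419629,0.000191982
29,0.000443213,0.000202678
30,0.000469328,0.000214617
31,0.000498248,0.000227944
32,0.000530271,0.000242821
33,0.000565733,0.000259427
34,0.000605,0.000277964
35,0.000648483,0.000298656
36,0.000696633,0.000321753
37,0.000749951,0.000347536
38,0.00080899,0.000376315
39,0.000874366,0.00040844
40,0.000946757,0.000444299
41,0.00102692,0.000484327
42,0.00111567,0.000529007
43,0.00121395,0.000578879
44,0.00132278,0.000634548
45,0.00144327,0.000696686
46,0.00157669,0.000766045
47,0.00172441,0.000843464
48,0.00188797,0.000929877
49,0.00206907,0.00102633
50,0.00226957,0.00113399
51,0.00249155,0.00125415
52,0.00273732,0.00138826
53,0.0030094,0.00153795
54,0.00331062,0.00170502
55,0.00364407,0.00189148
56,0.0040132,0.00209959
57,0.00442181,0.00233183
58,0.00487411,0.00259102
59,0.00537473,0.00288027
60,0.00592882,0.00320306
61,0.00654205,0.00356325
62,0.00722068,0.00396517
63,0.00797165,0.00441364
64,0.0088026,0.00491401
65,0.00972197,0.00547227
66,0.0107391,0.00609507
67,0.0118642,0.00678983
68,0.0131086,0.0075648
69,0.0144848,0.00842916
70,0.0160066,0.00939315
71,0.017689,0.0104681
72,0.0195488,0.0116667
73,0.0216041,0.0130029
74,0.0238751,0.0144924
75,0.0263839,0.0161525
76,0.0291545,0.0180022
77,0.0322135,0.0200629
78,0.0355896,0.0223581
79,0.0393146,0.0249139
80,0.0434228,0.027759
81,0.0479517,0.030925
82,0.0529419,0.0344471
83,0.0584374,0.0383635
84,0.0644858,0.0427166
85,0.0711384,0.0475526
86,0.0784503,0.0529221
87,0.0864801,0.0588801
88,0.0952906,0.0654867
89,0.104948,0.0728067
90,0.115522,0.0809102
91,0.127086,0.0898723
92,0.139716,0.0997733
93,0.153489,0.110698
94,0.168483,0.122737
95,0.184778,0.135984
96,0.20245,0.150534
97,0.221574,0.166488
98,0.242216,0.183942
99,0.264437,0.202995
100,0.288285,0.223738
101,0.313792,0.246256
102,0.340973,0.270622
103,0.369819,0.296892
104,0.400291,0.325101
105,0.432319,0.355255
106,0.465794,0.387326
107,0.500565,0.421246
108,0.536436,0.456897
109,0.57316,0.494106
110,1,1
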