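age,qx
0,0.004
1,3e-04
2,0.000265526
3,0.000235014
4,0.000208008
5,0.000184106
6,0.00016295
7,0.000144225
8,0.000127652
9,0.000112983
10,1e-04
11,0.00011487
12,0.000131951
13,0.000151572
14,0.00017411
15,2e-04
16,0.00022974
17,0.000263902
18,0.000303143
19,0.00034822
20,4e-04
21,0.000416552
22,0.000433789
23,0.000451739
24,0.000470432
25,0.000489898
26,0.00051017
27,0.00053128
28,0.000553265
29,0.000576159
30,6e-04
31,0.000643064
32,0.000689219
33,0.000738687
34,0.000791705
35,0.000848528
36,0.00090943
37,0.000974703
38,0.00104466
39,0.00111964
40,0.0012
41,0.00131515
42,0.00144135
43,0.00157966
44,0.00173124
45,0.00189737
46,0.00207943
47,0.00227897
48,0.00249766
49,0.00273733
50,0.003
51,0.00325342
52,0.00352824
53,0.00382627
54,0.00414949
55,0.0045
56,0.00491575
57,0.00536991
58,0.00586602
59,0.00640798
60,0.007
61,0.00766226
62,0.00838718
63,0.00918068
64,0.0100493
65,0.011
66,0.0120006
67,0.0130923
68,0.0142832
69,0.0155825
70,0.017
71,0.0187841
72,0.0207555
73,0.0229337
74,0.0253406
75,0.028
76,0.0311871
77,0.0347369
78,0.0386908
79,0.0430948
80,0.048
81,0.0538117
82,0.0603271
83,0.0676313
84,0.0758199
85,0.085
86,0.0952255
87,0.106681
88,0.119515
89,0.133893
90,0.15
91,0.164784
92,0.181025
93,0.198867
94,0.218468
95,0.24
96,0.258811
97,0.279096
98,0.300971
99,0.324561
100,0.35
101,0.377433
102,0.407015
103,0.438917
104,0.473319
105,0.510417
106,0.550423
107,0.593564
108,0.640087
109,0.690256
110,0.744358
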