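"age","qx"
0,0.000524862211614074
1,0.000527215330223485
2,0.000529790045745382
3,0.000532607225658177
4,0.000535689702373721
5,0.000539062458234096
6,0.000542752827921933
7,0.000546790719920365
8,0.000551208858815211
9,0.000556043050399579
10,0.000561332471724629
11,0.000567119988442166
12,0.000573452502004024
13,0.000580381329525315
14,0.000587962619380433
15,0.000596257805889122
16,0.000605334106763555
17,0.00061526506733367
18,0.000626131155940568
19,0.000638020415301033
20,0.000651029175094742
21,0.0006652628315168
22,0.00068083670007113
23,0.00069787694847312
24,0.000716521617160182
25,0.000736921735617013
26,0.000759242543477034
27,0.000783664826201624
28,0.000810386376041694
29,0.000839623589982463
30,0.00087161321745266
31,0.000906614271759754
32,0.000944910120500353
33,0.000986810771596791
34,0.00103265537313957
35,0.00108281494687912
36,0.00113769537702013
37,0.00119774067794742
38,0.00126343656664685
39,0.00133531436792178
40,0.00141395528302779
41,0.00149999505509346
42,0.00159412906767176
43,0.00169711791598182
44,0.00180979349389243
45,0.0019330656434593
46,0.00206792941789435
47,0.00221547301322578
48,0.00237688642861478
49,0.00255347092035907
50,0.00274664932002677
51,0.00295797729296277
52,0.003189155619579
53,0.00344204358840383
54,0.00371867359680766
55,0.00402126706264072
56,0.00435225175769594
57,0.00471428068191282
58,0.00511025260552012
59,0.00554333441481891
60,0.00601698540593998
61,0.00653498367955874
62,0.00710145479806656
63,0.00772090287489524
64,0.00839824427331481
65,0.00913884409879306
66,0.00994855567452335
67,0.0108337631935446
68,0.0118014277424237
69,0.0128591368900529
70,0.0140151580299002
71,0.0152784956540256
72,0.0166589527211348
73,0.0181671962574258
74,0.0198148272962889
75,0.0216144552189891
76,0.0235797765009078
77,0.0257256577939238
78,0.0280682231817971
79,0.0306249453281787
80,0.0334147400917242
81,0.0364580640047485
82,0.0397770137952286
83,0.0433954268703978
84,0.0473389813665974
85,0.0516352939967394
86,0.0563140134853741
87,0.0614069068632259
88,0.0669479352892469
89,0.0729733153700912
90,0.0795215611465102
91,0.0866335010072005
92,0.0943522627694003
93,0.102723219032359
94,0.111793883670954
95,0.121613749006698
96,0.132234051797837
97,0.143707454769821
98,0.15608762902185
99,0.169428721378596
100,0.183784689722868
101,0.199208488695528
102,0.21575108807696
103,0.233460306912272
104,0.252379448305954
105,0.272545723142227
106,0.293988456188287
107,0.316727075555171
108,0.340768896792482
109,0.366106726432927
110,1
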