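"age","qx"
0,0.000176439151084784
1,0.000177203982952845
2,0.000178059456540369
3,0.000179016313882618
4,0.000180086570040872
5,0.000181283663960641
6,0.000182622627207141
7,0.000184120272693766
8,0.000185795405773348
9,0.000187669060340956
10,0.000189764762911215
11,0.000192108827983484
12,0.000194730688401812
13,0.000197663264852488
14,0.000200943379136231
15,0.000204612216397115
16,0.000208715842106022
17,0.000213305780281114
18,0.000218439660193637
19,0.00022418193966689
20,0.000230604714031579
21,0.000237788620873536
22,0.000245823851906413
23,0.000254811284640777
24,0.000264863748014488
25,0.000276107437823137
26,0.000288683499653497
27,0.000302749799111823
28,0.000318482901466299
29,0.000336080285426754
30,0.000355762818691652
31,0.000377777526133549
32,0.000402400685120541
33,0.000429941286507085
34,0.00046074490434056
35,0.000495198022354426
36,0.000533732870927284
37,0.000576832834431551
38,0.000625038495855157
39,0.000678954393326991
40,0.000739256571795632
41,0.000806701022699419
42,0.000882133115114758
43,0.000966498133697202
44,0.00106085305184822
45,0.00116637968307443
46,0.00128439936959635
47,0.00141638938503885
48,0.00156400124765899
49,0.00172908116217541
50,0.00191369283201781
51,0.00212014290986773
52,0.0023510093828456
53,0.00260917321975851
54,0.00289785364153927
55,0.00322064741247718
56,0.00358157258904401
57,0.00398511720502959
58,0.00443629341613216
59,0.0049406976738241
60,0.00550457754675016
61,0.00613490585741583
62,0.00683946285147907
63,0.00762692716518809
64,0.00850697640152376
65,0.00949039816491726
66,0.0105892124347424
67,0.0118168061748717
68,0.0131880810749769
69,0.0147196152919877
70,0.0164298399983946
71,0.0183392314368656
72,0.0204705190141773
73,0.0228489097247478
74,0.0255023288541976
75,0.0284616764509389
76,0.0317610984380519
77,0.0354382704318835
78,0.0395346912943866
79,0.0440959821223268
80,0.0491721847096197
81,0.0548180514431701
82,0.0610933160349745
83,0.0680629313766044
84,0.0757972570482291
85,0.0843721745499494
86,0.0938691030898187
87,0.104374882730427
88,0.115981484882526
89,0.128785502633831
90,0.142887365420328
91,0.158390214452998
92,0.175398367692149
93,0.194015296894731
94,0.214341035602909
95,0.236468937613069
96,0.26048171272405
97,0.286446683266726
98,0.314410234505535
99,0.344391478388512
100,0.376375217399934
101,0.410304387169805
102,0.446072275488695
103,0.483514961341507
104,0.522404585966129
105,0.562444247528702
106,0.603265481371656
107,0.644429417135777
108,0.685432748194397
109,0.725719552741854
110,1
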