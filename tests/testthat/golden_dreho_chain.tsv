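voxel	value
0	1.6484978565570561
1	1.4903706141110515
2	1.2335037584711448
3	0.9601554024154525
4	1.0467629096225446
5	1.292172289585372
6	1.2722917247850114
7	1.132172436464876
8	0.95205078871211557
9	0.78453019880624064
10	0.87138555166941145
11	1.0546926251459419
12	1.1319552766753593
13	0.88293718259842391
14	0.72111278156279557
15	0.69471612472080524
16	0.77686399538682105
17	0.90140806778231075
18	1.140058152802236
19	0.88352299448965388
20	0.74476365879134376
21	0.75789510322758524
22	0.7732778854568001
23	0.85968501214709903
24	1.4095049629861924
25	1.0690125766426439
26	0.85460643032673456
27	0.79668381354887885
28	0.73798697868871632
29	0.79803591788618511
30	1.7488629829872302
31	1.2219607553175356
32	0.88383085133340811
33	0.78561742375478338
34	0.73152264892079932
35	0.8138574865947682
36	1.2399062371346281
37	1.1614412868617925
38	1.0149592204523861
39	0.78853746644279721
40	0.80737030735943682
41	0.95324537601604376
42	0.98490218295321874
43	0.90739404992302031
44	0.80381728282042419
45	0.66661714044440423
46	0.71205322909445956
47	0.84370687186263726
48	0.91367525613058398
49	0.74608121029704377
50	0.63898100547792225
51	0.62482474799218335
52	0.70407284322387897
53	0.83251041980078688
54	0.99316215602176228
55	0.79176236206670991
56	0.67779911131310544
57	0.69289818221852806
58	0.72954866278112585
59	0.84299422819560221
60	1.1561277037869686
61	0.89713697040446705
62	0.74852559249465977
63	0.76597097131148451
64	0.79994725666674193
65	0.93588614645613855
66	1.3233085470981143
67	0.96793379899776533
68	0.76984918059243657
69	0.80802168483908898
70	0.92496674505655974
71	1.1418573212181524
72	0.99278459890085302
73	0.98235274845359299
74	0.90821505438705741
75	0.72935550777382896
76	0.71592097084176576
77	0.8697570103628548
78	0.83157408876675887
79	0.80823499698753221
80	0.76912333909861041
81	0.68879678851126069
82	0.72503224178411241
83	0.85215403916993815
84	0.81364919451677831
85	0.70541722407019991
86	0.6497628460177669
87	0.68360408319169452
88	0.78800060024863428
89	0.91429365047457722
90	0.84889650313490184
91	0.69712707270432395
92	0.63124197807034332
93	0.69305694877627755
94	0.78364036903146139
95	0.91609287228648772
96	0.89739036850228238
97	0.74072139539616111
98	0.68716170294811241
99	0.80153286463474793
100	0.93620865540103848
101	1.131407126726617
102	0.97216927602332825
103	0.80119013295788832
104	0.7626263598944657
105	0.95125282949501233
106	1.2133381601887243
107	1.5286352140110244
108	1.0290624238621797
109	0.95564278079259546
110	0.90519650350743674
111	0.85167944527933959
112	0.93736376235373897
113	1.2585518116334062
114	0.93385223430560904
115	0.85914434452915822
116	0.83795211280008086
117	0.86297398035542705
118	0.95017448036773644
119	1.150921420037583
120	1.0560338318233111
121	0.88677396635584738
122	0.80294498864046437
123	0.87474725688586241
124	0.97916732384966987
125	1.0797361077139278
126	0.98445866024649242
127	0.80690325789119255
128	0.71976713194331199
129	0.78477702597115739
130	0.88084952351813206
131	0.98523217537170826
132	0.85835968116148353
133	0.74760686488378192
134	0.75098225808649
135	0.86462195125707464
136	0.96904881980688173
137	1.1310628629348261
138	0.88721533316197132
139	0.78939048102530718
140	0.89003423543874705
141	1.1080325895204417
142	1.2583341886974493
143	1.4813180028728337
144	1.2131276589999225
145	1.033639933355075
146	0.97335013765140932
147	1.0255821606784481
148	1.2180556369096192
149	1.6873336724838541
150	1.1497446453338727
151	0.98346453034591907
152	0.94437210672494343
153	1.0619620495554161
154	1.2063726346510717
155	1.4638671904387173
156	1.4361022267430212
157	1.1552533490008396
158	1.0025754737324326
159	1.1082904451233446
160	1.2049721464749099
161	1.267436120374746
162	1.3484237102753698
163	1.0793219998742805
164	0.90118720358827942
165	0.94373879784301407
166	1.0337138080370414
167	1.125964177537887
168	1.0948063912235473
169	0.94345080335549336
170	0.91052850721462508
171	0.97742322299398143
172	1.0587173502119638
173	1.2251619877368127
174	1.0571640664110966
175	0.94780910397016815
176	1.0950730359761329
177	1.2953223046517159
178	1.3728680927076244
179	1.5456512717070059
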