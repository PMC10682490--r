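node_id	network
1	SMN
2	SMN
3	SMN
4	SMN
5	SMN
6	SMN
7	SMN
8	SMN
9	SMN
10	SMN
11	SMN
12	SMN
13	SMN
14	SMN
15	SMN
16	SMN
17	SMN
18	SMN
19	SMN
20	SMN
21	SMN
22	SMN
23	SMN
24	SMN
25	SMN
26	SMN
27	SMN
28	SMN
29	SMN
30	SMN
31	SMN
32	SMN
33	SMN
34	SMN
35	CON
36	CON
37	CON
38	CON
39	CON
40	CON
41	CON
42	CON
43	CON
44	CON
45	CON
46	CON
47	CON
48	CON
49	AUD
50	AUD
51	AUD
52	AUD
53	AUD
54	AUD
55	AUD
56	AUD
57	AUD
58	AUD
59	AUD
60	AUD
61	AUD
62	DMN
63	DMN
64	DMN
65	DMN
66	DMN
67	DMN
68	DMN
69	DMN
70	DMN
71	DMN
72	DMN
73	DMN
74	DMN
75	DMN
76	DMN
77	DMN
78	DMN
79	DMN
80	DMN
81	DMN
82	DMN
83	DMN
84	DMN
85	DMN
86	DMN
87	DMN
88	DMN
89	DMN
90	DMN
91	DMN
92	DMN
93	DMN
94	DMN
95	DMN
96	DMN
97	DMN
98	DMN
99	DMN
100	DMN
101	DMN
102	DMN
103	DMN
104	DMN
105	DMN
106	DMN
107	DMN
108	DMN
109	DMN
110	DMN
111	DMN
112	DMN
113	DMN
114	DMN
115	DMN
116	DMN
117	DMN
118	DMN
119	DMN
120	VIS
121	VIS
122	VIS
123	VIS
124	VIS
125	VIS
126	VIS
127	VIS
128	VIS
129	VIS
130	VIS
131	VIS
132	VIS
133	VIS
134	VIS
135	VIS
136	VIS
137	VIS
138	VIS
139	VIS
140	VIS
141	VIS
142	VIS
143	VIS
144	VIS
145	VIS
146	VIS
147	VIS
148	VIS
149	VIS
150	VIS
151	FPN
152	FPN
153	FPN
154	FPN
155	FPN
156	FPN
157	FPN
158	FPN
159	FPN
160	FPN
161	FPN
162	FPN
163	FPN
164	FPN
165	FPN
166	FPN
167	FPN
168	FPN
169	FPN
170	FPN
171	FPN
172	FPN
173	FPN
174	FPN
175	FPN
176	SAN
177	SAN
178	SAN
179	SAN
180	SAN
181	SAN
182	SAN
183	SAN
184	SAN
185	SAN
186	SAN
187	SAN
188	SAN
189	SAN
190	SAN
191	SAN
192	SAN
193	SAN
194	SUB
195	SUB
196	SUB
197	SUB
198	SUB
199	SUB
200	SUB
201	SUB
202	SUB
203	SUB
204	SUB
205	SUB
206	SUB
207	VAN
208	VAN
209	VAN
210	VAN
211	VAN
212	VAN
213	VAN
214	VAN
215	VAN
216	DAN
217	DAN
218	DAN
219	DAN
220	DAN
221	DAN
222	DAN
223	DAN
224	DAN
225	DAN
226	DAN
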