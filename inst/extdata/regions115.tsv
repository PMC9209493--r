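id	name	hemisphere	set
1	Left-Cerebral-White-Matter	left	WM45
2	Left-Cerebellum-White-Matter	left	WM45
3	Left-Cerebellum-Cortex	left	WM45
4	Left-Lateral-Ventricle	left	WM45
5	Left-Inf-Lat-Vent	left	WM45
6	Left-Thalamus-Proper	left	WM45
7	Left-Caudate	left	WM45
8	Left-Putamen	left	WM45
9	Left-Pallidum	left	WM45
10	Left-Hippocampus	left	WM45
11	Left-Amygdala	left	WM45
12	Left-Accumbens-area	left	WM45
13	Left-VentralDC	left	WM45
14	Left-vessel	left	WM45
15	Left-choroid-plexus	left	WM45
16	Left-Cerebral-Cortex	left	WM45
17	Left-Insula-WM	left	WM45
18	Right-Cerebral-White-Matter	right	WM45
19	Right-Cerebellum-White-Matter	right	WM45
20	Right-Cerebellum-Cortex	right	WM45
21	Right-Lateral-Ventricle	right	WM45
22	Right-Inf-Lat-Vent	right	WM45
23	Right-Thalamus-Proper	right	WM45
24	Right-Caudate	right	WM45
25	Right-Putamen	right	WM45
26	Right-Pallidum	right	WM45
27	Right-Hippocampus	right	WM45
28	Right-Amygdala	right	WM45
29	Right-Accumbens-area	right	WM45
30	Right-VentralDC	right	WM45
31	Right-vessel	right	WM45
32	Right-choroid-plexus	right	WM45
33	Right-Cerebral-Cortex	right	WM45
34	Right-Insula-WM	right	WM45
35	3rd-Ventricle	none	WM45
36	4th-Ventricle	none	WM45
37	Brain-Stem	none	WM45
38	CSF	none	WM45
39	WM-hypointensities	none	WM45
40	Optic-Chiasm	none	WM45
41	CC_Posterior	none	WM45
42	CC_Mid_Posterior	none	WM45
43	CC_Central	none	WM45
44	CC_Mid_Anterior	none	WM45
45	CC_Anterior	none	WM45
101	ctx-lh-bankssts	left	CTX70
102	ctx-lh-caudalanteriorcingulate	left	CTX70
103	ctx-lh-caudalmiddlefrontal	left	CTX70
104	ctx-lh-cuneus	left	CTX70
105	ctx-lh-entorhinal	left	CTX70
106	ctx-lh-fusiform	left	CTX70
107	ctx-lh-inferiorparietal	left	CTX70
108	ctx-lh-inferiortemporal	left	CTX70
109	ctx-lh-isthmuscingulate	left	CTX70
110	ctx-lh-lateraloccipital	left	CTX70
111	ctx-lh-lateralorbitofrontal	left	CTX70
112	ctx-lh-lingual	left	CTX70
113	ctx-lh-medialorbitofrontal	left	CTX70
114	ctx-lh-middletemporal	left	CTX70
115	ctx-lh-parahippocampal	left	CTX70
116	ctx-lh-paracentral	left	CTX70
117	ctx-lh-parsopercularis	left	CTX70
118	ctx-lh-parsorbitalis	left	CTX70
119	ctx-lh-parstriangularis	left	CTX70
120	ctx-lh-pericalcarine	left	CTX70
121	ctx-lh-postcentral	left	CTX70
122	ctx-lh-posteriorcingulate	left	CTX70
123	ctx-lh-precentral	left	CTX70
124	ctx-lh-precuneus	left	CTX70
125	ctx-lh-rostralanteriorcingulate	left	CTX70
126	ctx-lh-rostralmiddlefrontal	left	CTX70
127	ctx-lh-superiorfrontal	left	CTX70
128	ctx-lh-superiorparietal	left	CTX70
129	ctx-lh-superiortemporal	left	CTX70
130	ctx-lh-supramarginal	left	CTX70
131	ctx-lh-temporalpole	left	CTX70
132	ctx-lh-transversetemporal	left	CTX70
133	ctx-lh-insula	left	CTX70
134	ctx-lh-frontalpole	left	CTX70
135	ctx-lh-corpuscallosum	left	CTX70
136	ctx-rh-bankssts	right	CTX70
137	ctx-rh-caudalanteriorcingulate	right	CTX70
138	ctx-rh-caudalmiddlefrontal	right	CTX70
139	ctx-rh-cuneus	right	CTX70
140	ctx-rh-entorhinal	right	CTX70
141	ctx-rh-fusiform	right	CTX70
142	ctx-rh-inferiorparietal	right	CTX70
143	ctx-rh-inferiortemporal	right	CTX70
144	ctx-rh-isthmuscingulate	right	CTX70
145	ctx-rh-lateraloccipital	right	CTX70
146	ctx-rh-lateralorbitofrontal	right	CTX70
147	ctx-rh-lingual	right	CTX70
148	ctx-rh-medialorbitofrontal	right	CTX70
149	ctx-rh-middletemporal	right	CTX70
150	ctx-rh-parahippocampal	right	CTX70
151	ctx-rh-paracentral	right	CTX70
152	ctx-rh-parsopercularis	right	CTX70
153	ctx-rh-parsorbitalis	right	CTX70
154	ctx-rh-parstriangularis	right	CTX70
155	ctx-rh-pericalcarine	right	CTX70
156	ctx-rh-postcentral	right	CTX70
157	ctx-rh-posteriorcingulate	right	CTX70
158	ctx-rh-precentral	right	CTX70
159	ctx-rh-precuneus	right	CTX70
160	ctx-rh-rostralanteriorcingulate	right	CTX70
161	ctx-rh-rostralmiddlefrontal	right	CTX70
162	ctx-rh-superiorfrontal	right	CTX70
163	ctx-rh-superiorparietal	right	CTX70
164	ctx-rh-superiortemporal	right	CTX70
165	ctx-rh-supramarginal	right	CTX70
166	ctx-rh-temporalpole	right	CTX70
167	ctx-rh-transversetemporal	right	CTX70
168	ctx-rh-insula	right	CTX70
169	ctx-rh-frontalpole	right	CTX70
170	ctx-rh-corpuscallosum	right	CTX70
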