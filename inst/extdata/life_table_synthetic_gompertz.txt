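age	annual_death_prob
63	0.00422433182976822
64	0.00459823924685931
65	0.00500515899881371
66	0.00544799033965415
67	0.00592988429205454
68	0.00645426498110568
69	0.00702485267688335
70	0.00764568866389159
71	0.00832116205987277
72	0.00905603871021277
73	0.0098554922869688
74	0.01072513772312
75	0.0116710671126121
76	0.0126998882047151
77	0.0138187656166011
78	0.0150354648802752
79	0.0163583994282989
80	0.0177966806062895
81	0.0193601707779111
82	0.0210595395588199
83	0.0229063231783743
84	0.0249129869202596
85	0.0270929905336277
86	0.0294608564327642
87	0.0320322404132095
88	0.0348240045028816
89	0.0378542914349327
90	0.0411426000713004
91	0.0447098609182947
92	0.0485785106538473
93	0.0527725643256478
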