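roi_id	label	hemisphere	networks
1	AC	M	FPN;DMN
2	MidFG.L	L	FPN
3	MidFG.R	R	FPN
4	SFG.L	L	FPN
5	SFG.R	R	FPN
6	aSMG.L	L	DMN
7	aSMG.R	R	DMN
8	pSMG.L	L	DMN
9	pSMG.R	R	DMN
10	MedFC	M	DMN
11	PC	M	DMN
12	FOrb.L	L	RMN
13	FOrb.R	R	RMN
14	Caudate.L	L	RMN
15	Caudate.R	R	RMN
16	Putamen.L	L	RMN
17	Putamen.R	R	RMN
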