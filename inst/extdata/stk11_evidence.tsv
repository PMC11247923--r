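variant_id	gnomad_af	luciferase_result	gel_shift_result	revel	colocated	clinvar_definitive	printed_total	printed_category
p.G56W		LoF	LoF	0.932		FALSE	7	LP
p.P179R		LoF	LoF	0.939	P179Q:LP:0.94	FALSE	8	LP
p.S193Y		LoF	LoF	0.871		FALSE	5	VUS-high
p.S216F		LoF	LoF	0.954		FALSE	7	LP
p.P221R		LoF	LoF	0.892		FALSE	5	VUS-high
p.F148S		LoF	LoF	0.728		FALSE	4	VUS-high
p.A241P		LoF	LoF	0.782		FALSE	5	VUS-high
p.R297M		LoF	LoF	0.936	R297S:P:0.94	FALSE	9	LP
p.H202R	3.16E-06	LoF	WT-like	0.424		FALSE	0	VUS-low
p.W308R		LoF	LoF	0.881	W308C:LP:0.73;W308L:LP:0.84	FALSE	7	LP
p.G242V		LoF	LoF	0.97	G242R:P:0.97	FALSE	9	LP
p.G251C		LoF	LoF	0.833		FALSE	5	VUS-high
p.S31F		WT-like	WT-like	0.8		FALSE	1	VUS-low
p.P275L		WT-like	WT-like	0.663		FALSE	0	VUS-low
p.K84del	4.34E-06	WT-like	WT-like			FALSE	-2	LB
p.R211Q	1.81E-05	WT-like	WT-like	0.215		FALSE	-3	LB
p.Q112E	1.24E-06	WT-like	WT-like	0.393		FALSE	-2	LB
p.G155R	1.90E-06	WT-like	WT-like	0.382		FALSE	-2	LB
p.R104G	3.72E-06	WT-like	WT-like	0.582		FALSE	-2	LB
p.R409W	4.28E-05	WT-like	WT-like	0.238		FALSE	-3	LB
p.A417S	1.02E-05	WT-like	WT-like	0.102		FALSE	-4	LB
p.A397S	1.87E-05	WT-like	WT-like	0.03		FALSE	-4	LB
p.P280A		WT-like	WT-like	0.097		FALSE	-3	LB
p.K311N		WT-like	WT-like	0.461		FALSE	-1	LB
p.D194Y		LoF	LoF	0.929	D194H:P:0.94;D194V:P:0.94;D194E:P:0.84	TRUE	9	LP
p.G163R		LoF	LoF	0.933	G163D:P:0.95	TRUE	7	LP
p.R297S		LoF	LoF	0.936		TRUE	7	LP
p.F354L	5.10E-03	WT-like	WT-like	0.156		TRUE	-8	B
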