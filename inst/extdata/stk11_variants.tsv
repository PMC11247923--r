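variant_id	genomic_hgvs	variant_class	clinvar	hgmd	gnomad_ac	gnomad_af	mean_r_wt	q25	q75	label	gel_shift_label	gel_shift_note	excluded_from_evaluation
p.D194Y	chr19:g.1220487G>T	missense	P/LP	DM			-0.09	-0.24	0.08	LoF	LoF		TRUE
p.G56W	chr19:g.1207078G>T	missense	none	none			-0.08	-0.1	0	LoF	LoF		FALSE
p.P179R	chr19:g.1220443C>G	missense	none	DM			-0.01	-0.04	0.1	LoF	LoF		TRUE
p.S193Y	chr19:g.1220485C>A	missense	none	none			0.02	-0.02	0.15	LoF	LoF		FALSE
p.S216F	chr19:g.1220629C>T	missense	VUS	none			0.15	0.01	0.36	LoF	LoF		FALSE
p.P221R	chr19:g.1220644C>G	missense	none	none			0.19	0.04	0.37	LoF	LoF		FALSE
p.F148S	chr19:g.1219391T>C	missense	none	none			0.20	-0.03	0.44	LoF	LoF		FALSE
p.G163R	chr19:g.1220394G>C	missense	LP	DM			0.22	0.06	0.32	LoF	LoF		TRUE
p.A241P	chr19:g.1220703G>C	missense	none	DM			0.27	0.09	0.46	LoF	LoF		TRUE
p.R297M	chr19:g.1221975G>T	missense	none	none			0.32	0.17	0.43	LoF	LoF		FALSE
p.H202R	chr19:g.1220587A>G	missense	VUS	none	5	3.16E-06	0.34	0.19	0.49	LoF	WT-like		FALSE
p.W308R	chr19:g.1222985T>C	missense	VUS	none			0.38	0.19	0.52	LoF	LoF		FALSE
p.G242V	chr19:g.1220707G>T	missense	none	DM?			0.38	0.31	0.43	LoF	LoF		FALSE
p.R297S	chr19:g.1221976G>T	missense	P	none			0.41	0.32	0.49	LoF	LoF		TRUE
p.G251C	chr19:g.1221228G>T	missense	none	none			0.56	0.36	0.79	LoF	LoF	weak	FALSE
p.S31F	chr19:g.1207004C>T	missense	none	none			0.69	0.56	0.89	WT-like	WT-like		FALSE
p.P275L	chr19:g.1221301C>T	missense	VUS	none			0.81	0.72	0.91	WT-like	WT-like		FALSE
p.K84del	chr19:g.1207153_1207155delAAG	inframe_deletion	VUS	none	7	4.34E-06	0.90	0.61	1.09	WT-like	WT-like		FALSE
p.R211Q	chr19:g.1220614G>A	missense	VUS/LB	none	29	1.81E-05	1.00	0.79	1.18	WT-like	WT-like		FALSE
p.Q112E	chr19:g.1218459C>G	missense	VUS	none	2	1.24E-06	1.06	0.69	1.17	WT-like	WT-like		FALSE
p.G155R	chr19:g.1219411G>A	missense	VUS	none	3	1.90E-06	1.07	0.8	1.13	WT-like	WT-like		FALSE
p.R104G	chr19:g.1218435A>G	missense	VUS	none	6	3.72E-06	1.08	0.92	1.18	WT-like	WT-like		FALSE
p.R409W	chr19:g.1226569C>T	missense	VUS/LB	DM?	68	4.28E-05	1.11	0.91	1.18	WT-like	WT-like		FALSE
p.A417S	chr19:g.1226593G>T	missense	VUS	none	16	1.02E-05	1.29	0.86	1.66	WT-like	WT-like		FALSE
p.A397S	chr19:g.1226533G>T	missense	VUS/LB	DM?	30	1.87E-05	1.30	0.93	1.6	WT-like	WT-like		FALSE
p.P280A	chr19:g.1221315C>G	missense	VUS	none			1.47	1.39	1.68	WT-like	WT-like		FALSE
p.F354L	chr19:g.1223125C>G	missense	B/LB	DM?	8225	5.10E-03	1.51	0.93	1.88	WT-like	WT-like		TRUE
p.K311N	chr19:g.1222996G>T	missense	none	none			1.62	1.25	2.03	WT-like	WT-like		FALSE
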