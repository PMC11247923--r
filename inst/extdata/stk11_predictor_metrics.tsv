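predictor	group	pearson	pearson_lo	pearson_hi	kendall_tau	kendall_lo	kendall_hi	auc	auc_lo	auc_hi
3Cnet	participant	0.783	0.624	0.909	0.584	0.390	0.757	0.933	0.800	1.000
Evolutionary Action	participant	0.756	0.592	0.886	0.515	0.280	0.710	0.825	0.654	0.975
Protein language model	participant	0.186	-0.093	0.675	0.411	0.213	0.590	0.775	0.567	0.967
Bologna Biocomputing	participant	0.321	-0.064	0.655	0.264	-0.056	0.569	0.733	0.567	0.875
REVEL	baseline	0.821	0.705	0.916	0.662	0.473	0.829	0.950	0.867	1.000
AlphaMissense	baseline	0.704	0.414	0.920	0.610	0.417	0.790	0.925	0.825	1.000
MutPred2	baseline	0.682	0.557	0.811	0.547	0.352	0.705	0.933	0.817	1.000
PolyPhen-2	baseline	0.613	0.417	0.786	0.487	0.283	0.675	0.883	0.727	1.000
EVE	baseline	0.613	0.368	0.796	0.396	0.199	0.605	0.858	0.700	0.983
Experimental-Max	ceiling	0.836	0.734	0.917	0.681	0.558	0.784	0.964	0.900	1.000
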