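breed	n_samples	SROH_mb	NROH	MNROH_mb	MNROH_sd
Baier	18	1977.998	686	2.845	0.645
Chahua	19	2698.555	837	3.227	0.405
Fighting	20	2328.759	975	2.353	0.401
Gushi	20	2745.876	886	3.006	0.643
Langshan	20	571.271	296	1.921	0.303
WanTy	20	181.114	91	2.010	0.692
Wugu	20	2645.142	917	2.885	0.576
Xiaoshan	20	1775.372	554	2.989	0.724
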