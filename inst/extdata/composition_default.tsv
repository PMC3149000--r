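mu	protein	RNA	DNA	lipid	LPS	murein	glycogen	other	D_ATP	D_NADPH	D_NADH
0.1	0.58	0.105	0.035	0.091	0.034	0.025	0.025	0.105	20	2	3
0.2	0.56	0.135	0.031	0.091	0.034	0.025	0.025	0.099	20	2	3
0.3	0.54	0.165	0.029	0.091	0.034	0.025	0.025	0.091	20	2	3
0.4	0.52	0.195	0.027	0.091	0.034	0.025	0.025	0.083	20	2	3
0.5	0.52	0.2	0.026	0.091	0.034	0.025	0.025	0.079	20	2	3
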