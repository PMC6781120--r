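trait	matrix	sigma2_a0	sigma2_a1	sigma_a01	sigma2_pe	sigma2_hy	sigma2_e	r_a0a1
AIS	A	0.083	0.046	-0.054	0.052	0.052	1.40	-0.880
AIS	H	0.076	0.044	-0.050	0.052	0.010	1.40	-0.871
ICF	A	92.0	0.015	-0.849	53.3	38.7	728.1	-0.724
ICF	H	95.5	0.016	-0.883	52.1	38.7	728.2	-0.725
IFL	A	48.0	0.052	-0.621	168.2	18.3	3383.1	-0.395
IFL	H	44.7	0.050	-0.535	166.6	18.3	3383.9	-0.360
NRR	A	0.006	0.009	-0.005	0.004	0.001	0.235	-0.709
NRR	H	0.005	0.009	-0.005	0.004	0.001	0.235	-0.690
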