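class	phi	psi	weight
generic	-63	-43	0.1
generic	-70	-35	0.1
generic	-57	-47	0.1
generic	-120	130	0.1
generic	-135	150	0.1
generic	-110	125	0.1
generic	-75	145	0.133333333333333
generic	-65	150	0.133333333333333
generic	-70	155	0.133333333333333
glycine	-80	170	0.25
glycine	80	-170	0.25
glycine	-170	170	0.25
glycine	170	-170	0.25
proline	-65	150	0.7
proline	-65	-30	0.3
preproline	-70	150	0.45
preproline	-130	155	0.45
preproline	-60	-30	0.1
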