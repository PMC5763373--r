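transcript	c_true	theta_true	w_true	group
t1	1	0.00664662694098448	0.0825220693227198	1
t2	1	0.338694808290814	0.262819365909079	1
t3	0	0.0921383779673135	0.0921383779673135	1
t4	0	0.00275434709895481	0.00275434709895481	1
t5	0	0.308740737422508	0.308740737422508	2
t6	0	0.193658128061563	0.193658128061563	2
t7	0	0.0458589605162099	0.0458589605162099	2
t8	0	0.0115080137016515	0.0115080137016515	2
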