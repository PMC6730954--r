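cross	chr	pos_cM	eval_peak	beta_sc	beta_co	alpha_sc	alpha_co	beta_prime_sc	beta_prime_co	t_sc	t_co	f_sc	f_co	p_sc_analytic	p_co_analytic	p_sc_empirical	p_co_empirical
cast_x_musc	4	44.0	sc	3.73	0.48	7.2e-3	1.46	2.96	0.24	2.32	3.33	0.21	0.50	0.021	8.7e-4	<1e-3	<1e-3
cast_x_musc	4	25.0	co	3.06	0.48	4.2e-3	1.81	1.96	0.37	2.73	2.63	0.36	0.23	0.006	0.009	<1e-3	<1e-3
cast_x_musc	X	31.9	sc	-3.67	-1.74	7.2e-3	1.46	-1.08	-1.48	-4.92	-4.18	0.70	0.15	8.7e-7	2.9e-5	<1e-3	<1e-3
cast_x_musc	X	33.0	co	-3.38	-1.65	4.2e-3	1.81	-0.36	-1.50	-4.17	-3.22	0.89	0.10	3.1e-5	1.3e-3	<1e-3	<1e-3
dom_x_dom	5	44.8	sc	0.80	-0.31	1.8e-3	1.21	1.17	-0.32	-1.99	1.15	-0.46	-0.03	0.047	0.249	0.04	0.08
dom_x_dom	5	36.9	co	0.08	-0.34	9.5e-4	0.80	0.35	-0.34	-1.25	0.13	-3.38	0.06	0.210	0.896	0.19	0.92
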