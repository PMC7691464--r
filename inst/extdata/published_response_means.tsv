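species	class	trait	units	G1	G2_pred	Re_pct	G2_minus	G2_plus	Delta_pct	sig_cov	sig_var	score_based
petraea	Growth	CIRC	cm	190.83	200.94	5.30	32.43	33.52	3.32	TRUE	TRUE	FALSE
petraea	Growth	HGHT	cm	2655.22	2696.84	1.57	1089.00	1106.573	1.60	TRUE	TRUE	FALSE
petraea	Phenology	LU	days/score	106.21	106.31	0.095	3.92	3.92	0.13	FALSE	FALSE	TRUE
petraea	Physiology	C	g/kg	454.74	443.51	-2.47	458.69	458.178	-0.11	TRUE	TRUE	FALSE
petraea	Physiology	C/N	ratio	24.53	24.77	0.99	19.29	19.132	-0.83	FALSE	FALSE	FALSE
petraea	Physiology	d13C	permil	-29.77	-29.73	0.14	-29.46	-29.59	0.44	FALSE	FALSE	FALSE
petraea	Physiology	d15N	permil	-3.35	-3.25	2.87	-6.42	-6.46	0.65	FALSE	FALSE	FALSE
petraea	Physiology	MLA	cm2	44.78	47.13	5.25	32.21	32.51	0.92	TRUE	FALSE	FALSE
petraea	Physiology	N	g/kg	18.84	18.44	-2.17	24.03	24.14	0.47	FALSE	FALSE	FALSE
petraea	Physiology	SLA	m2/kg	11.93	11.48	-3.76	13.21	13.49	2.12	TRUE	FALSE	FALSE
petraea	Structure	WD	kg/m3	576.77	569.87	-1.20	506.97	509.31	0.46	FALSE	FALSE	FALSE
robur	Growth	CIRC	cm	167.19	168.47	0.76	26.695	27.455	2.81	FALSE	FALSE	FALSE
robur	Growth	HGHT	cm	2516.41	2474.53	-1.66	924.252	945.46	2.27	TRUE	TRUE	FALSE
robur	Phenology	LU	days/score	101.80	101.28	-0.50	3.687	3.685	-0.05	FALSE	FALSE	TRUE
robur	Physiology	C	g/kg	461.31	461.59	0.06	465.434	465.098	-0.07	FALSE	FALSE	FALSE
robur	Physiology	C/N	ratio	23.69	23.88	0.80	20.205	19.991	-1.06	FALSE	FALSE	FALSE
robur	Physiology	d13C	permil	-30.08	-30.00	0.27	-29.657	-29.713	-0.19	FALSE	FALSE	FALSE
robur	Physiology	d15N	permil	-2.32	-2.22	4.39	-3.904	-4.156	-6.25	FALSE	FALSE	FALSE
robur	Physiology	MLA	cm2	35.78	32.72	-8.53	22.773	23.351	2.51	TRUE	TRUE	FALSE
robur	Physiology	N	g/kg	19.84	NA	NA	23.362	23.579	0.92	FALSE	FALSE	FALSE
robur	Physiology	SLA	m2/kg	13.82	NA	NA	13.49	13.866	2.75	FALSE	FALSE	FALSE
robur	Structure	WD	kg/m3	549.69	543.78	-1.07	498.269	497.628	-0.13	FALSE	FALSE	FALSE
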