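community	taxon	reference	miseq	r9	r94	bias_miseq	bias_r9	bias_r94
HM782D	Acinetobacter spp.	0.050	0.019	0.046	0.032	-1.42	-0.12	-0.62
HM782D	Actinomyces spp.	0.050	0.010	0.001	0.003	-2.36	-5.36	-4.02
HM782D	Bacillus spp.	0.050	0.017	0.102	0.045	-1.57	1.03	-0.16
HM782D	Bacteroides spp.	0.050	0.106	0.059	0.037	1.08	0.25	-0.42
HM782D	Clostridium spp.	0.050	0.125	0.027	0.032	1.32	-0.91	-0.66
HM782D	Deinococcus spp.	0.050	0.109	0.000	0.000	1.12	ND	ND
HM782D	Enterococcus spp.	0.050	0.022	0.012	0.013	-1.17	-2.04	-1.93
HM782D	Escherichia/Shigella spp.	0.050	0.038	0.172	0.209	-0.38	1.79	2.07
HM782D	Helicobacter spp.	0.050	0.040	0.000	0.000	-0.32	ND	ND
HM782D	Lactobacillus spp.	0.050	0.065	0.051	0.068	0.38	0.03	0.45
HM782D	Listeria spp.	0.050	0.024	0.074	0.133	-1.04	0.57	1.41
HM782D	Neisseria spp.	0.050	0.099	0.064	0.056	0.98	0.36	0.17
HM782D	Propionibacterium spp.	0.050	0.021	0.079	0.097	-1.25	0.66	0.96
HM782D	Pseudomonas spp.	0.050	0.038	0.018	0.079	-0.39	-1.46	0.67
HM782D	Rhodobacter spp.	0.050	0.013	0.002	0.004	-1.91	-4.36	-3.51
HM782D	Staphylococcus spp.	0.100	0.037	0.125	0.086	-1.44	0.32	-0.22
HM782D	Streptococcus spp.	0.150	0.217	0.115	0.093	0.53	-0.38	-0.69
D6305	Bacillus spp.	0.139	0.574	0.383	0.340	2.04	1.46	1.29
D6305	Enterococcus spp.	0.088	0.078	0.057	0.082	-0.17	-0.64	-0.11
D6305	Escherichia/Shigella spp.	0.113	0.035	0.167	0.137	-1.67	0.56	0.28
D6305	Lactobacillus spp.	0.198	0.104	0.049	0.049	-0.93	-2.01	-2.01
D6305	Listeria spp.	0.163	0.046	0.080	0.118	-1.82	-1.03	-0.46
D6305	Pseudomonas spp.	0.058	0.060	0.038	0.039	0.05	-0.62	-0.56
D6305	Salmonella spp.	0.115	0.049	0.099	0.138	-1.22	-0.22	0.26
D6305	Staphylococcus spp.	0.126	0.051	0.094	0.095	-1.30	-0.42	-0.41
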