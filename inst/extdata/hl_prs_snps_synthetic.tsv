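snp	weight	weight_se	freq
rs_syn01	0.35	0.045	0.26
rs_syn02	0.22	0.038	0.41
rs_syn03	0.18	0.032	0.33
rs_syn04	0.41	0.060	0.12
rs_syn05	0.27	0.042	0.19
rs_syn06	0.15	0.028	0.47
rs_syn07	0.31	0.050	0.22
rs_syn08	0.19	0.035	0.38
rs_syn09	0.24	0.040	0.29
rs_syn10	0.45	0.065	0.09
rs_syn11	0.16	0.030	0.52
rs_syn12	0.29	0.044	0.24
rs_syn13	0.21	0.036	0.35
rs_syn14	0.38	0.055	0.14
rs_syn15	0.17	0.031	0.44
rs_syn16	0.26	0.041	0.27
rs_syn17	0.33	0.052	0.18
rs_syn18	0.20	0.034	0.40
rs_syn19	0.23	0.039	0.31
rs_syn20	0.28	0.043	0.21
rs_syn21	0.36	0.053	0.16
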