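analyte	control_mean	control_sd	control_n	case_mean	case_sd	case_n	printed_p	printed_p_adj
IL-1b	39	13	6	25	14	8	0.06	0.38
IL-2	76	54	6	37	36	8	0.16	0.38
MIP-1a	70	47	6	38	24	8	0.17	0.38
TNFa	63113	22374	6	44931	25191	8	0.18	0.38
IL-5	13808	4924	6	9853	5524	8	0.18	0.38
IL-17	489	174	6	349	196	8	0.18	0.38
KC	1134	404	6	809	454	8	0.18	0.38
MCP-1	9539	3402	6	6807	3817	8	0.18	0.38
IL-3	1090	576	6	696	465	8	0.20	0.38
GM-CSF	406	197	6	280	142	8	0.22	0.38
IL-12p40	1826	1585	6	899	675	8	0.22	0.38
IL-4	196	133	6	116	89	8	0.24	0.38
Eotaxin	1451	704	6	1023	559	8	0.25	0.38
IL-9	1343	761	6	896	540	8	0.25	0.38
IL-13	36765	47127	6	12128	8241	8	0.26	0.38
G-CSF	2282	1714	6	1340	975	8	0.26	0.38
IFNg	80672	43806	6	56155	36511	8	0.29	0.40
MIP-1b	2743	2317	6	1561	1557	8	0.31	0.40
IL-1a	54	64	6	25	47	8	0.37	0.44
IL-10	3634	1492	6	2824	1956	8	0.40	0.44
IL-12p70	2725	3173	6	1328	2548	8	0.40	0.44
IL-6	274	197	6	204	252	8	0.57	0.60
RANTES	170	226	6	113	222	8	0.65	0.65
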