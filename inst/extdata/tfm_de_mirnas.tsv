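mirna	fold_change	p
miR-148b-3p	2.79	8.33E-05
miR-222-3p	2.51	1.05E-04
miR-4711-3p	3.82	1.20E-04
let-7a-5p	2.44	1.78E-04
miR-128-3p	3.24	2.28E-04
let-7d-5p	2.61	2.77E-04
let-7c-5p	2.01	5.24E-04
miR-328-3p	2.51	5.54E-04
let-7i-5p	2.61	6.14E-04
miR-191-5p	3.14	6.51E-04
miR-31-5p	2.92	7.02E-04
miR-320a	2.01	8.85E-04
miR-32-5p	4.76	1.05E-03
miR-130b-3p	2.42	1.15E-03
let-7e-5p	2.52	1.33E-03
miR-340-5p	3.12	1.36E-03
HK_RPL27	4.06	1.43E-03
miR-17-5p	2.13	1.45E-03
miR-339-5p	2.43	1.50E-03
let-7g-5p	2.77	1.56E-03
miR-744-5p	2.80	1.77E-03
miR-15a-5p	2.66	1.81E-03
miR-18a-5p	3.03	1.93E-03
miR-652-3p	2.26	1.97E-03
miR-5089-3p	4.58	2.18E-03
miR-130a-3p	2.70	2.19E-03
miR-4420	4.60	2.22E-03
miR-25-3p	2.10	2.39E-03
miR-26b-5p	2.14	2.55E-03
miR-22-3p	2.55	2.58E-03
miR-16-5p	2.66	2.82E-03
miR-181d-5p	2.81	3.04E-03
miR-142-5p	2.32	3.36E-03
miR-484	2.24	3.49E-03
miR-26a-5p	2.35	3.51E-03
miR-92a-3p	2.53	3.77E-03
miR-106b-5p	2.15	3.79E-03
miR-326	2.02	3.93E-03
miR-15b-5p	3.01	4.73E-03
miR-93-5p	2.15	4.85E-03
let-7f-5p	2.97	4.91E-03
miR-29b-3p	2.44	5.06E-03
miR-107	2.95	5.58E-03
miR-19b-3p	2.36	5.60E-03
miR-548a-5p	6.18	5.74E-03
miR-27a-3p	2.02	6.38E-03
miR-185-5p	2.29	6.63E-03
miR-4649-3p	2.33	6.72E-03
miR-486-5p	2.01	7.25E-03
miR-6754-3p	2.55	7.28E-03
miR-6754-5p	2.32	7.76E-03
miR-106a-5p	2.52	7.80E-03
miR-6855-3p	4.54	8.06E-03
miR-181b-5p	2.66	8.15E-03
miR-221-3p	2.03	8.44E-03
miR-19a-3p	2.22	8.45E-03
miR-6778-5p	2.80	9.53E-03
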