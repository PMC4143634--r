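window_kb	marker	in_gene	assoc_p	n_rv	calpha_stat	perm_p
1	35751033	1	0.00064	5	-31.83	0.090
5	35751033	1	0.00064	27	-100.25	0.276
25	35751033	1	0.00064	154	-939.73	0.629
1	212007	1	0.00174	6	1.29	0.207
5	212007	1	0.00174	20	-2.14	0.437
25	212007	1	0.00174	101	-27.57	0.485
1	262976	1	0.00214	0	n/a	n/a
5	262976	1	0.00214	4	1.86	0.070
25	262976	1	0.00214	34	10.96	0.002
1	53856668	1	0.00192	7	-0.42	0.367
5	53856668	1	0.00192	22	-2.80	0.507
25	53856668	1	0.00192	104	-62.61	0.329
1	1464118	1	0.00220	1	n/a	n/a
5	1464118	1	0.00220	3	-1.28	0.891
25	1464118	1	0.00220	27	-25.29	0.658
1	5020216	0	0.00141	13	1.91	0.008
5	5020216	0	0.00141	50	-0.11	0.415
25	5020216	0	0.00141	127	-35.27	0.935
1	3953247	0	0.00158	1	n/a	n/a
5	3953247	0	0.00158	9	-33.10	0.091
25	3953247	0	0.00158	53	-23.10	0.245
1	11719665	0	0.00173	4	1.94	<0.001
5	11719665	0	0.00173	23	16.35	0.037
25	11719665	0	0.00173	64	23.23	0.041
1	4553960	0	0.00186	4	-2.22	0.407
5	4553960	0	0.00186	10	-4.37	0.440
25	4553960	0	0.00186	47	-1.37	0.009
1	34366649	0	0.00222	2	-6.40	0.227
5	34366649	0	0.00222	9	-5.46	0.161
25	34366649	0	0.00222	15	36.97	0.030
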