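comparison	contig	length_bp	fold_change	male_sample	male_rpkm	female_sample_1	female_rpkm_1	female_sample_2	female_rpkm_2	source
B	contig_22537	1546	-109.63	BJ2	185.79	BJ3	0.1	BJ4	3.29	fungal
B	contig_26828	407	-90.35	BJ2	145.56	BJ3	0	BJ4	3.22	annelid
B	contig_30721	521	-44.23	BJ2	68.22	BJ3	0.39	BJ4	2.7	fungal
B	contig_47470	424	-100.05	BJ2	111.08	BJ3	0.12	BJ4	2.1	fungal
B	contig_49000	222	-39.38	BJ2	131.19	BJ3	0.96	BJ4	5.71	fungal
D	contig_31948	667	-387.12	BJ6	64.8	BJ7	0.1	BJ8	0.23	bacterial
D	contig_3465	234	-20.53	BJ6	29.21	BJ7	0.57	BJ8	2.28	ribosomal
D	contig_41160	210	-70.11	BJ6	37.85	BJ7	0.33	BJ8	0.75	bacterial
D	contig_567	220	-23.73	BJ6	33.44	BJ7	2.82	BJ8	0	eve
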