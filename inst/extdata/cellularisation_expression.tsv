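transcript	contig	length_bp	BJ5	BJ6	BJ7	BJ8	BJ1	BJ2	BJ3	BJ4
nullo	consensus	1332	1.15	2.52	0.13	15.34	8.59	162.77	125.03	45.74
srya	9105	5007	13.31	11.32	10.66	9.64	12.42	4.22	3.5	4.31
slam	3824	5366	2.02	0.76	0.25	13.35	35.87	460.96	425.02	299.29
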