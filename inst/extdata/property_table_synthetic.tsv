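# Synthetic stand-in for a 20x13 amino-acid physicochemical descriptor matrix.
# Columns are 13 published AAindex scales (accession ids in the header) chosen to
# span hydrophobic, electronic, hydrogen-bond and steric character; values are the
# raw AAindex entries. Standardize (per-column z-score) before encoding.
residue	KYTJ820101	HOPT810101	EISD840101	PONP800101	GRAR740102	ZIMJ680104	KLEP840101	FAUJ880109	FAUJ880110	BIGC670101	CHOC760101	CHAM810101	FASG760101
A	1.80	-0.50	0.25	12.28	8.10	6.00	0.00	0.00	0.00	52.60	115.00	0.52	89.09
C	2.50	-1.00	0.04	14.93	5.50	5.05	0.00	0.00	0.00	68.30	135.00	0.62	121.15
D	-3.50	3.00	-0.72	10.97	13.00	2.77	-1.00	1.00	4.00	68.40	150.00	0.76	133.10
E	-3.50	3.00	-0.62	11.19	12.30	3.22	-1.00	1.00	4.00	84.70	190.00	0.68	147.13
F	2.80	-2.50	0.61	13.43	5.20	5.48	0.00	0.00	0.00	113.90	210.00	0.70	165.19
G	-0.40	0.00	0.16	12.01	9.00	5.97	0.00	0.00	0.00	36.30	75.00	0.00	75.07
H	-3.20	-0.50	-0.40	12.84	10.40	7.59	0.00	1.00	1.00	91.90	195.00	0.70	155.16
I	4.50	-1.80	0.73	14.77	5.20	6.02	0.00	0.00	0.00	102.00	175.00	1.02	131.17
K	-3.90	3.00	-1.10	10.80	11.30	9.74	1.00	2.00	1.00	105.10	200.00	0.68	146.19
L	3.80	-1.80	0.53	14.10	4.90	5.98	0.00	0.00	0.00	102.00	170.00	0.98	131.17
M	1.90	-1.30	0.26	14.33	5.70	5.74	0.00	0.00	0.00	97.70	185.00	0.78	149.21
N	-3.50	0.20	-0.64	11.00	11.60	5.41	0.00	2.00	3.00	75.70	160.00	0.76	132.12
P	-1.60	0.00	-0.07	11.19	8.00	6.30	0.00	0.00	0.00	73.60	145.00	0.36	115.13
Q	-3.50	0.20	-0.69	11.28	10.50	5.65	0.00	2.00	3.00	89.70	180.00	0.68	146.15
R	-4.50	3.00	-1.76	11.49	10.50	10.76	1.00	4.00	3.00	109.10	225.00	0.68	174.20
S	-0.80	0.30	-0.26	11.26	9.20	5.68	0.00	1.00	2.00	54.90	115.00	0.53	105.09
T	-0.70	-0.40	-0.18	11.65	8.60	5.66	0.00	1.00	2.00	71.20	140.00	0.50	119.12
V	4.20	-1.50	0.54	15.07	5.90	5.96	0.00	0.00	0.00	85.10	155.00	0.76	117.15
W	-0.90	-3.40	0.37	12.95	5.40	5.89	0.00	1.00	0.00	135.40	255.00	0.70	204.24
Y	-1.30	-2.30	0.02	13.29	6.20	5.66	0.00	1.00	2.00	116.20	230.00	0.70	181.19
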