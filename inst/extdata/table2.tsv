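complex	bond_no	loop	residue	atom	partner_residue	partner_atom	equ1	equ2	equ3	max	ave	std
Complex I-N-truncated	1	FG	PRO130	O	THR56_L	N	0.77	0.74	0.71	0.77	0.74	0.03
Complex I-N-truncated	2	FG	ALA129	O	THR56_L	OG1	0.60	0.57	0.61	0.61	0.59	0.02
Complex I-N-truncated	3	FG	LYS131	NZ	ASP101_H	OD1	0.34	0.42	0.39	0.42	0.38	0.04
Complex I-N-truncated	4	FG	LYS131	NZ	ASP101_H	OD2	0.40	0.29	0.31	0.40	0.33	0.06
Complex I-N-truncated	5	BC	GLU61	OE1	TYR102_H	OH	0.21	0.38	0.42	0.42	0.34	0.11
Complex I-N-truncated	6	BC	GLU61	OE2	TYR102_H	OH	0.30	0.25	0.38	0.38	0.31	0.07
Complex I-N-truncated	7	BC	GLU61	OE1	THR28_H	OG1	0.15	0.29	0.01	0.29	0.15	0.14
Complex I-N-truncated	8	BC	GLU61	OE2	THR28_H	OG1	0.08	0.26	0.14	0.26	0.16	0.09
Complex I-N-truncated	9	BC	GLU61	N	GLY26_H	O	0.18	0.23	0.20	0.23	0.20	0.03
Complex II-N-truncated	10	FG	PRO130	O	THR56_L	N	0.75	0.47	0.71	0.75	0.64	0.15
Complex II-N-truncated	11	FG	LYS131	NZ	ASP101_H	OD1	0.52	0.46	0.33	0.52	0.44	0.10
Complex II-N-truncated	12	FG	ALA129	O	THR56_L	OG1	0.52	0.32	0.10	0.52	0.31	0.21
Complex II-N-truncated	13	FG	LYS131	NZ	ASP101_H	OD2	0.29	0.27	0.33	0.33	0.30	0.03
Complex II-N-truncated	14	FG	LYS131	N	ASP100_H	O	0.03	0.34	0.06	0.34	0.14	0.17
Complex II-N-truncated	15	FG	LYS135	NZ	ASP100_H	OD1	0.00	0.32	0.00	0.32	0.11	0.18
Complex II-N-truncated	16	FG	LYS131	NZ	ASN99_H	O	0.09	0.26	0.02	0.26	0.12	0.12
Complex II-N-truncated	17	FG	GLN133	OE1	TYR49_L	OH	0.03	0.20	0.05	0.20	0.09	0.09
Complex II-N-truncated	18	BC	GLU61	N	GLY26_H	O	0.03	0.28	0.05	0.28	0.12	0.14
Complex II-N-truncated	19	BC	GLU61	N	THR28_H	OG1	0.00	0.02	0.22	0.22	0.08	0.12
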