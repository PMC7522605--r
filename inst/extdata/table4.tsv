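complex	bond_no	loop	residue	atom	partner_residue	partner_atom	equ1	equ2	equ3	max	ave	std
Complex I-IgV-rotated	1	N-terminal	ASP29	OD1	GLY33_H	N	0.22	0.41	0.95	0.95	0.53	0.38
Complex I-IgV-rotated	2	N-terminal	ARG30	N	ASN31_H	O	0.84	0.82	0.71	0.84	0.79	0.07
Complex I-IgV-rotated	3	N-terminal	ASP29	OD2	GLY33_H	N	0.68	0.49	0.00	0.68	0.39	0.35
Complex I-IgV-rotated	4	N-terminal	ASP29	OD2	ASN99_H	ND2	0.23	0.44	0.64	0.64	0.44	0.21
Complex I-IgV-rotated	5	N-terminal	ASP29	OD1	ASN99_H	ND2	0.55	0.41	0.22	0.55	0.39	0.17
Complex I-IgV-rotated	6	N-terminal	PRO28	O	TYR53_H	N	0.25	0.29	0.29	0.29	0.28	0.02
Complex I-IgV-rotated	7	N-terminal	ARG30	NH1	ASN31_H	OD1	0.20	0.15	0.05	0.20	0.13	0.08
Complex II-IgV-rotated	8	N-terminal	ASP29	OD1	GLY33_H	N	0.95	0.06	0.24	0.95	0.42	0.47
Complex II-IgV-rotated	9	N-terminal	ASP29	OD2	GLY33_H	N	0.00	0.90	0.70	0.90	0.53	0.47
Complex II-IgV-rotated	10	N-terminal	ARG30	N	ASN31_H	O	0.84	0.82	0.80	0.84	0.82	0.02
Complex II-IgV-rotated	11	N-terminal	ASP29	OD1	ASN99_H	ND2	0.17	0.67	0.49	0.67	0.44	0.25
Complex II-IgV-rotated	12	N-terminal	ASP29	OD2	ASN99_H	ND2	0.63	0.17	0.31	0.63	0.37	0.24
Complex II-IgV-rotated	13	N-terminal	ARG30	NH1	ASN31_H	OD1	0.19	0.04	0.36	0.36	0.20	0.16
Complex II-IgV-rotated	14	N-terminal	PRO28	O	TYR53_H	N	0.26	0.19	0.29	0.29	0.25	0.05
Complex II-IgV-rotated	15	N-terminal	ARG30	NE	ASN31_H	OD1	0.28	0.14	0.06	0.28	0.16	0.11
Complex II-IgV-rotated	16	N-terminal	ASP26	OD1	LYS57_H	NZ	0.07	0.09	0.20	0.20	0.12	0.07
Complex II-IgV-rotated	17	FG	LYS131	NZ	ASP101_H	OD1	0.49	0.00	0.01	0.49	0.17	0.28
Complex II-IgV-rotated	18	FG	LYS131	NZ	ASN99_H	O	0.28	0.00	0.09	0.28	0.12	0.14
Complex II-IgV-rotated	19	FG	LYS131	NZ	ASP101_H	OD2	0.22	0.00	0.26	0.26	0.16	0.14
Complex II-IgV-rotated	20	FG	PRO130	O	THR56_L	N	0.18	0.00	0.21	0.21	0.13	0.11
Complex II-IgV-rotated	21	FG	LYS131	NZ	ASP50_L	OD1	0.00	0.20	0.01	0.20	0.07	0.11
Complex II-IgV-rotated	22	BC	GLU61	OE1	THR28_H	OG1	0.08	0.32	0.00	0.32	0.13	0.17
Complex II-IgV-rotated	23	BC	GLU61	OE2	THR28_H	N	0.03	0.31	0.00	0.31	0.11	0.17
Complex II-IgV-rotated	24	BC	GLU61	OE1	THR28_H	N	0.02	0.25	0.00	0.25	0.09	0.14
Complex II-IgV-rotated	25	BC	GLU61	OE2	THR28_H	OG1	0.13	0.23	0.01	0.23	0.12	0.11
Complex II-IgV-rotated	26	BC	THR59	O	ASN31_H	ND2	0.22	0.06	0.13	0.22	0.14	0.08
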