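complex	bond_no	loop	residue	atom	partner_residue	partner_atom	equ1	equ2	equ3	max	ave	std
Complex I-N-rotated	1	N-terminal	ARG30	NH1	ASN31_H	O	0.00	0.00	0.75	0.75	0.25	0.43
Complex I-N-rotated	2	N-terminal	PRO28	O	TYR53_H	OH	0.00	0.01	0.60	0.60	0.20	0.34
Complex I-N-rotated	3	N-terminal	ARG30	NH1	ASP100_H	OD1	0.02	0.03	0.54	0.54	0.20	0.30
Complex I-N-rotated	4	N-terminal	ARG30	NH2	ASP100_H	OD2	0.02	0.09	0.48	0.48	0.20	0.25
Complex I-N-rotated	5	N-terminal	ARG30	NH2	ASP100_H	OD1	0.00	0.05	0.24	0.24	0.10	0.13
Complex I-N-rotated	6	N-terminal	ARG30	NH1	ASP100_H	OD2	0.01	0.02	0.23	0.23	0.09	0.12
Complex I-N-rotated	7	FG	PRO130	O	THR56_L	N	0.65	0.71	0.65	0.71	0.67	0.03
Complex I-N-rotated	8	FG	ALA129	O	THR56_L	OG1	0.41	0.53	0.43	0.53	0.46	0.06
Complex I-N-rotated	9	FG	LYS131	NZ	ASP101_H	OD1	0.27	0.44	0.49	0.49	0.40	0.12
Complex I-N-rotated	10	FG	LYS131	NZ	ASP101_H	OD2	0.48	0.21	0.25	0.48	0.31	0.15
Complex I-N-rotated	11	FG	LYS131	NZ	ASN99_H	O	0.14	0.13	0.23	0.23	0.17	0.06
Complex I-N-rotated	12	BC	GLU61	N	GLY26_H	O	0.00	0.43	0.00	0.43	0.14	0.25
Complex I-N-rotated	13	BC	GLU61	OE1	TYR102_H	OH	0.01	0.39	0.00	0.39	0.13	0.22
Complex I-N-rotated	14	BC	GLU61	OE2	TYR102_H	OH	0.03	0.25	0.00	0.25	0.09	0.14
Complex II-N-rotated	15	N-terminal	ARG30	NH1	ASN31_H	O	0.00	0.00	0.62	0.62	0.21	0.36
Complex II-N-rotated	16	N-terminal	ARG30	NE	ASN31_H	OD1	0.52	0.00	0.00	0.52	0.17	0.30
Complex II-N-rotated	17	N-terminal	LEU25	O	TYR53_H	OH	0.00	0.52	0.00	0.52	0.17	0.30
Complex II-N-rotated	18	N-terminal	ARG30	NH1	ASP100_H	OD2	0.00	0.00	0.41	0.41	0.14	0.24
Complex II-N-rotated	19	N-terminal	ARG30	NH2	ASP100_H	OD1	0.00	0.00	0.40	0.40	0.13	0.23
Complex II-N-rotated	20	N-terminal	ARG30	NH1	ASP100_H	OD1	0.00	0.01	0.38	0.38	0.13	0.22
Complex II-N-rotated	21	N-terminal	ARG30	NH2	ASP100_H	OD2	0.00	0.00	0.38	0.38	0.13	0.22
Complex II-N-rotated	22	N-terminal	ASP26	OD1	LYS57_H	NZ	0.24	0.02	0.05	0.24	0.10	0.12
Complex II-N-rotated	23	FG	PRO130	O	THR56_L	N	0.62	0.78	0.81	0.81	0.74	0.10
Complex II-N-rotated	24	FG	LYS131	NZ	ASP101_H	OD2	0.43	0.32	0.50	0.50	0.42	0.09
Complex II-N-rotated	25	FG	ALA129	O	THR56_L	OG1	0.14	0.32	0.40	0.40	0.29	0.13
Complex II-N-rotated	26	FG	LYS131	NZ	ASP101_H	OD1	0.19	0.20	0.32	0.32	0.24	0.07
Complex II-N-rotated	27	FG	LYS131	N	ASP100_H	O	0.26	0.11	0.03	0.26	0.13	0.12
Complex II-N-rotated	28	BC	GLU61	N	GLN1_H	OY	0.00	0.00	0.27	0.27	0.09	0.16
Complex II-N-rotated	29	BC	THR59	OG1	GLY26_H	O	0.00	0.00	0.22	0.22	0.07	0.13
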