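complex	bond_no	loop	residue	atom	partner_residue	partner_atom	equ1	equ2	equ3	max	ave	std
Complex I	1	N-terminal	ASP29	OD1	GLY33_H	N	0.41	0.72	0.80	0.80	0.76	0.06
Complex I	2	N-terminal	ARG30	N	ASN31_H	O	0.52	0.70	0.76	0.76	0.66	0.12
Complex I	3	N-terminal	ASP29	OD2	ASN99_H	ND2	0.32	0.61	0.66	0.66	0.53	0.18
Complex I	4	N-terminal	ASP29	OD1	ASN99_H	ND2	0.37	0.15	0.08	0.37	0.20	0.15
Complex I	5	N-terminal	ASP29	OD2	GLY33_H	N	0.36	0.02	0.00	0.36	0.13	0.20
Complex I	6	N-terminal	PRO28	O	TYR53_H	N	0.28	0.16	0.21	0.28	0.22	0.06
Complex I	7	FG	ALA129	O	THR56_L	OG1	0.30	0.57	0.64	0.64	0.50	0.18
Complex I	8	FG	PRO130	O	THR56_L	N	0.50	0.62	0.56	0.62	0.56	0.06
Complex I	9	FG	LYS131	NZ	ASP101_H	OD2	0.36	0.27	0.29	0.36	0.31	0.05
Complex I	10	FG	LYS131	N	ASP100_H	O	0.35	0.28	0.32	0.35	0.32	0.04
Complex I	11	FG	LYS131	NZ	ASP101_H	OD1	0.26	0.32	0.31	0.32	0.30	0.03
Complex I	12	BC	GLU61	OE2	THR28_H	OG1	0.01	0.43	0.39	0.43	0.28	0.23
Complex I	13	BC	GLU61	OE2	THR28_H	N	0.00	0.41	0.31	0.41	0.24	0.21
Complex I	14	BC	GLU61	OE1	THR28_H	OG1	0.01	0.32	0.31	0.32	0.21	0.18
Complex I	15	BC	GLU61	OE1	THR28_H	N	0.00	0.24	0.28	0.28	0.17	0.15
Complex II	16	N-terminal	ARG30	N	ASN31_H	O	0.82	0.76	0.25	0.82	0.61	0.31
Complex II	17	N-terminal	ASP29	OD2	GLY33_H	N	0.59	0.00	0.11	0.59	0.23	0.31
Complex II	18	N-terminal	ASP29	OD1	ASN99_H	ND2	0.52	0.23	0.33	0.52	0.36	0.15
Complex II	19	N-terminal	ARG30	NH1	ASN31_H	OD1	0.45	0.03	0.00	0.45	0.16	0.25
Complex II	20	N-terminal	ASP29	OD2	ASN99_H	ND2	0.29	0.14	0.42	0.42	0.28	0.14
Complex II	21	N-terminal	ASP29	OD1	GLY33_H	N	0.36	0.01	0.28	0.36	0.22	0.18
Complex II	22	N-terminal	PRO28	O	TYR53_H	N	0.21	0.09	0.27	0.27	0.19	0.09
Complex II	23	N-terminal	ASP26	OD2	LYS57_H	NZ	0.09	0.10	0.24	0.24	0.14	0.08
Complex II	24	N-terminal	ASP26	OD1	LYS57_H	NZ	0.06	0.24	0.17	0.24	0.16	0.09
Complex II	25	FG	PRO130	O	THR56_L	N	0.28	0.68	0.60	0.68	0.52	0.21
Complex II	26	FG	LYS131	NZ	ASP101_H	OD2	0.50	0.18	0.28	0.50	0.32	0.16
Complex II	27	FG	LYS131	NZ	ASP101_H	OD1	0.35	0.38	0.42	0.42	0.38	0.04
Complex II	28	FG	ALA129	O	THR56_L	OG1	0.08	0.29	0.06	0.29	0.14	0.13
Complex II	29	FG	LYS131	NZ	ASN99_H	O	0.25	0.15	0.16	0.25	0.19	0.06
Complex II	30	BC	THR59	O	THR28_H	N	0.00	0.53	0.05	0.53	0.19	0.29
Complex II	31	BC	GLU61	N	GLY26_H	O	0.00	0.42	0.04	0.42	0.15	0.23
Complex II	32	BC	GLU61	N	THR28_H	OG1	0.01	0.00	0.32	0.32	0.11	0.18
Complex II	33	BC	THR59	O	ASN31_H	ND2	0.05	0.01	0.27	0.27	0.11	0.14
Complex II	34	BC	SER60	OG	GLY26_H	O	0.00	0.27	0.01	0.27	0.09	0.15
Complex II	35	BC	THR59	OG1	ASN31_H	ND2	0.01	0.21	0.03	0.21	0.08	0.11
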