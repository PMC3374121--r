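haplogroup	subgroup	stage	study	or	ci_low	ci_high
E1b1b1c	overall	I	StageI	0.51	0.30	0.87
E1b1b1c	overall	II	Einstein	0.82	0.63	1.07
E1b1b1c	overall	II	MSKCC	0.87	0.52	1.46
E1b1b1c	overall	II	PHS	0.73	0.32	1.67
E1b1b1c	overall	II	HPFS	0.70	0.23	2.18
E1b1b1c	nonaggressive	I	StageI	0.33	0.13	0.86
E1b1b1c	nonaggressive	II	Einstein	0.66	0.45	0.95
E1b1b1c	nonaggressive	II	MSKCC	0.96	0.47	1.94
E1b1b1c	nonaggressive	II	PHS	0.57	0.16	2.02
E1b1b1c	nonaggressive	II	HPFS	1.12	0.36	3.49
E1b1b1c	aggressive	I	StageI	0.59	0.32	1.09
E1b1b1c	aggressive	II	Einstein	0.94	0.68	1.29
E1b1b1c	aggressive	II	MSKCC	0.98	0.53	1.83
E1b1b1c	aggressive	II	PHS	0.85	0.28	2.63
E1b1b1c	aggressive	II	HPFS	0.00	0.00	1.77
R1b1a2	overall	I	StageI	0.90	0.81	1.00
R1b1a2	overall	II	Einstein	1.25	0.94	1.67
R1b1a2	overall	II	MSKCC	1.02	0.61	1.71
R1b1a2	overall	II	PHS	1.14	0.88	1.47
R1b1a2	overall	II	AHS	0.96	0.78	1.17
R1b1a2	nonaggressive	I	StageI	0.97	0.84	1.13
R1b1a2	nonaggressive	II	Einstein	1.30	0.91	1.87
R1b1a2	nonaggressive	II	MSKCC	0.99	0.51	1.93
R1b1a2	nonaggressive	II	PHS	1.23	0.87	1.72
R1b1a2	nonaggressive	II	AHS	0.88	0.66	1.09
R1b1a2	aggressive	I	StageI	0.90	0.79	1.02
R1b1a2	aggressive	II	Einstein	1.17	0.82	1.69
R1b1a2	aggressive	II	MSKCC	1.06	0.59	1.92
R1b1a2	aggressive	II	PHS	1.15	0.81	1.65
R1b1a2	aggressive	II	AHS	1.09	0.69	1.74
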