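allotype	peptide	mean_tm	sd_tm	n
B5701	LSSPVTKSF	70.6	0.74	4
B5701	LSSPVTQSF	70.4	0.26	2
B5701	LSSPVTKSW	72.6	0.41	4
B5701	LSSPVTQSW	73.1	0.18	2
B5701	LTVQVARVY	69.4	0.18	2
B5701	LTVQVAQVY	67.1	0.18	2
B5701	LTVQVARVW	72.2	0.46	4
B5701	LTVQVAQVW	71.0	0.48	4
B5701	SAAADETLRLW	67.5	0.99	4
B5703	LSSPVTKSF	69.2	0.35	4
B5703	LSSPVTQSF	69.6	0.11	2
B5703	LSSPVTKSW	71.0	0	4
B5703	LSSPVTQSW	71.1	0.1	4
B5703	LTVQVARVY	60.6	0.67	4
B5703	LTVQVAQVY	63.1	0.14	4
B5703	LTVQVARVW	69.2	0.09	4
B5703	LTVQVAQVW	70.9	0.19	4
B5703	SAAADETLRLW	61.3	0.17	4
B5801	LSSPVTKSF	69.3	0.52	4
B5801	LSSPVTQSF	70.2	0.7	4
B5801	LSSPVTKSW	71.8	0.61	4
B5801	LSSPVTQSW	73.0	0.32	4
B5801	LTVQVARVW	67.8	1.12	4
B5801	LTVQVAQVW	72.4	0.61	8
B5801	SAAADETLRLW	64.4	0.67	4
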