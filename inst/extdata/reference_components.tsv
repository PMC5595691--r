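species	rank	het_code	name	targets	global_identity	site_identity	aging	domain_cons	site_cons	affinity	bioavailability	lipinski_loss	promiscuity_loss	purchase_bonus	approval_bonus	final	kd_nm
dmelanogaster	1	1N1	dasatinib	BMX,BTK,MK14	67	100	1	0.96	1	0.95	0.9	0	0	0.1	0.1	1.00	NA
dmelanogaster	2	CT5	NA	HSP90a	77	92	0.98	0.97	1	0.95	0.9	0	0	0.1	0.08	0.99	NA
dmelanogaster	3	I47	NA	MK14	67	100	1	0.96	1	0.93	0.9	0	0	0.1	0.08	0.98	NA
dmelanogaster	4	SB4	NA	MK14	67	100	1	0.96	1	0.92	0.9	0	0	0.1	0.08	0.97	NA
dmelanogaster	5	TAK	dorsomorphin	AMPKa2	56	100	1	0.97	1	0.9	0.9	0	0	0.1	0.08	0.96	63
dmelanogaster	6	STI	imatinib	ABL1,MK14	67	94	1	0.97	0.99	0.88	0.9	0	0	0.1	0.1	0.95	100
dmelanogaster	7	P01	purvalanol	S6Ka1	46	100	1	0.96	1	0.89	0.9	0	0	0.1	0.08	0.95	NA
dmelanogaster	8	P37	NA	MK14	67	94	1	0.96	0.95	0.94	0.9	0	0	0.1	0.08	0.95	NA
dmelanogaster	9	JNF	NA	MK10	62	100	1	0.97	1	0.87	0.9	0	0	0.1	0.08	0.94	120
dmelanogaster	10	BAX	sorafenib	MK14	68	95	1	0.96	0.99	0.92	0.9	-0.05	0	0.1	0.1	0.94	35
dmelanogaster	11	JNK	NA	MK10	62	100	1	0.97	1	0.92	0.9	-0.05	0	0.1	0.08	0.93	NA
dmelanogaster	12	I45	NA	MK14	67	88	1	0.96	0.93	0.94	0.9	0	0	0.1	0.08	0.93	NA
dmelanogaster	13	BSM	NA	HSP90a	77	88	0.98	0.97	0.93	0.94	0.9	0	0	0.1	0.08	0.92	NA
dmelanogaster	14	GVP	NA	AKT2	49	78	1	0.96	0.91	0.93	0.9	0	0	0.1	0.08	0.91	NA
dmelanogaster	15	NIL	nilotinib	ABL1,MK11	61	100	1	0.97	1	0.93	0.9	-0.1	0	0.1	0.1	0.91	NA
celegans	1	STI	imatinib	ABL1,MAPK14	62	91	1	0.96	0.99	0.88	0.97	0	0	0.1	0.1	1.00	NA
celegans	2	NIL	nilotinib	ABL1,MAPK11	59	83	1	0.95	0.96	0.93	0.95	-0.1	0	0.1	0.1	0.91	23
celegans	3	GVP	NA	AKT2	49	78	1	0.95	0.95	0.93	0.81	0	0	0.1	0.08	0.86	NA
celegans	4	BAX	sorafenib	MK14	62	82	1	0.92	0.92	0.92	0.74	-0.05	0	0.1	0.1	0.72	NA
celegans	5	X6K	PI-103	MTOR	31	100	1	0.94	1	0.93	0.69	0	0	0.1	0	0.71	NA
celegans	6	BMU	NA	MK14	62	88	1	0.96	0.95	0.85	0.68	0	0	0.1	0.08	0.71	NA
celegans	7	DG7	NA	MK14	62	93	1	0.96	0.94	0.94	0.87	-0.05	0	0	0	0.69	NA
celegans	8	JBI	NA	MK10	45	93	1	0.97	1	0.91	0.83	-0.05	0	0	0	0.68	NA
celegans	9	TAK	dorsomorphin	AMPKa2	51	91	1	0.97	0.92	0.9	0.6	0	0	0.1	0.08	0.66	NA
celegans	10	9HP	NA	MK10	45	100	1	0.97	1	0.88	0.66	0	0	0	0.08	0.63	NA
celegans	11	GK3	NA	MK14	61	79	1	0.96	0.88	0.87	0.78	-0.05	0	0	0.08	0.6	NA
celegans	12	BI5	NA	MK14	62	75	1	0.96	0.87	0.79	0.64	0	0	0.1	0.08	0.6	NA
celegans	13	JNF	NA	MK10	45	100	1	0.97	1	0.87	0.5	0	0	0.1	0.08	0.6	NA
celegans	14	D94	NA	IGF1R	20	75	1	0.87	0.83	0.9	0.95	-0.05	0	0	0	0.57	NA
celegans	15	YI0	NA	HSP90a	74	86	0.98	0.97	0.92	0.88	0.74	0	0	0	0	0.56	NA
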