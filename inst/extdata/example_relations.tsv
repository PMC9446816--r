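pmid	sent_id	sentence	e1_text	e1_start	e1_end	e1_type	e2_text	e2_start	e2_end	e2_type	label
SYN00001	0	GENE45 inhibits MIR111	GENE45	0	6	gene	MIR111	16	22	rna	negative_cause
SYN00001	1	PROT58 correlates with PROT98 in a dose dependent manner	PROT58	0	6	protein	PROT98	23	29	protein	undirected_link
SYN00001	2	PROT138 binds PROT182 levels in a dose dependent manner	PROT138	0	7	protein	PROT182 levels	14	28	protein	undirected_link
SYN00001	3	CMPD48 modulates MIR35	CMPD48	0	6	compound	MIR35	17	22	rna	directed_link
SYN00002	0	GENE173 suppresses GENE189	GENE173	0	7	gene	GENE189	19	26	gene	negative_cause
SYN00002	1	MIR71 levels modulates MIR155 expression	MIR71 levels	0	12	rna	MIR155 expression	23	40	rna	directed_link
SYN00002	2	GENE17 stimulates CMPD136	GENE17	0	6	gene	CMPD136	18	25	compound	positive_cause
SYN00002	3	silencing of CMPD180 inhibits a decrease in GENE105 expression in tumor cells	CMPD180	13	20	compound	GENE105 expression	44	62	gene	negative_decrease
SYN00003	0	GENE45 modulates CMPD4	GENE45	0	6	gene	CMPD4	17	22	compound	directed_link
SYN00003	1	GENE113 stimulates MIR179 expression in a dose dependent manner	GENE113	0	7	gene	MIR179 expression	19	36	rna	positive_cause
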