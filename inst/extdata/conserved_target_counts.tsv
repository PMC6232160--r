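family	conserved	osa	zma	ath	vvi	novel
MIR156	50	48	45	40	47	4
MIR160	11	10	9	9	10	0
MIR166	11	11	11	11	11	1
MIR169	77	75	77	68	58	6
MIR171	2	2	2	2	2	0
MIR172	74	74	74	51	60	28
MIR319	0	0	0	0	0	3
MIR393	19	19	19	19	19	2
MIR444	120	118	110	.	.	21
MIR529	11	10	1	.	.	7
MIR827	15	15	15	0	.	0
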