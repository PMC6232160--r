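family	os_loci	n_loci	breakdown
MIR156	12	8	a(1), b(1), c(1), g(3), j(1), k(1)
MIR160	6	4	b(3), c(1)
MIR166	13	2	a(2)
MIR167	10	5	d(2), g(3)
MIR169	18	16	a(1), c(3), i(1), n(3), p(1), q(7)
MIR171	9	5	a(1), c(2), f(1), i(1)
MIR172	4	3	b(1), d(2)
MIR319	2	2	a(2)
MIR393	2	4	a(1), b(3)
MIR396	8	2	a(1), b(1)
MIR444	6	12	a(2), c(4), d(5), e(1)
MIR529	2	1	a(1)
MIR827	1	1	*(1)
MIR1430	1	4	*(4)
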