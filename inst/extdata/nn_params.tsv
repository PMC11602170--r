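type	key	dg
stack	AA/UU	-0.9
stack	AU/UA	-1.1
stack	AC/UG	-2.2
stack	AG/UC	-2.1
stack	AG/UU	-0.6
stack	AU/UG	-1.4
stack	UA/AU	-1.3
stack	UU/AA	-0.9
stack	UC/AG	-2.4
stack	UG/AC	-2.1
stack	UG/AU	-1
stack	UU/AG	-1.3
stack	CA/GU	-2.1
stack	CU/GA	-2.1
stack	CC/GG	-3.3
stack	CG/GC	-2.4
stack	CG/GU	-1.4
stack	CU/GG	-2.1
stack	GA/CU	-2.4
stack	GU/CA	-2.2
stack	GC/CG	-3.4
stack	GG/CC	-3.3
stack	GG/CU	-1.5
stack	GU/CG	-2.5
stack	GA/UU	-1.3
stack	GU/UA	-1.4
stack	GC/UG	-2.5
stack	GG/UC	-2.1
stack	GG/UU	-0.5
stack	GU/UG	1.3
stack	UA/GU	-1
stack	UU/GA	-0.6
stack	UC/GG	-1.5
stack	UG/GC	-1.4
stack	UG/GU	0.3
stack	UU/GG	-0.5
hairpin	3	5.4
hairpin	4	5.6
hairpin	5	5.7
hairpin	6	5.4
hairpin	7	6
hairpin	8	5.5
hairpin	9	6.4
hairpin	10	6.5
hairpin	11	6.6
hairpin	12	6.7
hairpin	13	6.8
hairpin	14	6.9
hairpin	15	6.9
hairpin	16	7
hairpin	17	7.1
hairpin	18	7.1
hairpin	19	7.2
hairpin	20	7.2
hairpin	21	7.3
hairpin	22	7.3
hairpin	23	7.4
hairpin	24	7.4
hairpin	25	7.5
hairpin	26	7.5
hairpin	27	7.5
hairpin	28	7.6
hairpin	29	7.6
hairpin	30	7.7
misc	terminal_au	0.5
misc	lxc	1.07856
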