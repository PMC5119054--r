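sentence	dep_order	dep_word	dep_pos	gov_order	gov_word	gov_pos	deprel
1	1	This	pro	2	Is	v	subj
1	2	Is	v
1	3	An	det	4	Example	n	atr
1	4	Example	n	2	Is	v	obj
2	5	This	pro	6	Example	n	atr
2	6	Example	n	7	Is	v	subj
2	7	Is	v
2	8	Very	adv	9	Convincing	adj	adva
2	9	Convincing	adj	6	Is	n	obj
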