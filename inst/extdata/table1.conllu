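# sent_id = s1
1	This	_	pro	_	_	2	subj	_	_
2	Is	_	v	_	_	0	root	_	_
3	An	_	det	_	_	4	atr	_	_
4	Example	_	n	_	_	2	obj	_	_

# sent_id = s2
1	This	_	pro	_	_	2	atr	_	_
2	Example	_	n	_	_	3	subj	_	_
3	Is	_	v	_	_	0	root	_	_
4	Very	_	adv	_	_	5	adva	_	_
5	Convincing	_	adj	_	_	2	obj	_	_
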