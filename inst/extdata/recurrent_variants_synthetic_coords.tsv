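family_id	gene	chrom	pos	ref	alt	hgvs_c	hgvs_p	functional_class
I	CHST15	10	125780000	AC	A	c.1366delC	p.R456fs	frameshift
I	TBX10	11	67890000	C	T	c.791C>T	p.P264L	missense
II	HOXA4	7	27168520	A	C	c.920A>C	p.H307P	missense
II	MUC6	11	1017000	C	T	c.4553C>T	p.T1518I	missense
II	MUC6	11	1016500	C	T	c.5705C>T	p.T1902I	missense
III	HOXA4	7	27168520	A	C	c.920A>C	p.H307P	missense
III	CHST15	10	125780100	A	AGCCC	c.1356_1357insGCCC	p.P453fs	frameshift
III	AMER1	X	63412000	C	T	c.61C>T	p.R21C	missense
IV	MUC6	11	1016500	C	T	c.5705C>T	p.T1902I	missense
V	HOXA4	7	27168520	A	C	c.920A>C	p.H307P	missense
V	MUC6	11	1017000	C	T	c.4553C>T	p.T1518I	missense
V	AMER1	X	63412000	C	T	c.61C>T	p.R21C	missense
VI	CHST15	10	125780000	AC	A	c.1366delC	p.R456fs	frameshift
VI	TBX10	11	67890000	C	T	c.791C>T	p.P264L	missense
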