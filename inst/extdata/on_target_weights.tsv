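position	token	weight
0	(intercept)	0.10
4	A	0.05
4	G	-0.07
5	G	0.10
5	T	-0.06
6	C	-0.08
7	A	0.04
9	G	0.07
10	A	0.09
10	T	-0.10
12	C	-0.12
14	A	0.06
14	G	-0.06
15	T	-0.08
16	C	-0.25
17	G	0.12
18	A	0.10
18	C	-0.10
19	G	0.15
19	T	-0.20
20	C	-0.22
20	G	0.10
21	T	-0.25
21	G	0.12
22	C	-0.18
22	A	0.08
23	G	0.25
23	T	-0.30
24	G	0.60
24	C	-0.45
24	T	-0.25
25	C	0.15
25	T	-0.20
28	G	0.18
28	T	-0.12
29	C	-0.05
30	A	0.04
5	CC	-0.10
11	TT	-0.20
16	TG	0.08
19	GG	-0.15
23	GG	-0.10
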