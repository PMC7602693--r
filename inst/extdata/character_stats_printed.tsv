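char	l	ci	ri	additive	pref
1	7	0.28	0.70	FALSE	none
2	1	1	1	FALSE	none
3	3	0.66	0.80	TRUE	none
4	2	1	1	FALSE	none
5	1	1	1	FALSE	none
6	2	0.50	0.80	FALSE	none
7	2	0.50	0.50	FALSE	acctran
8	3	0.66	0.83	FALSE	deltran
9	2	0.50	0.80	FALSE	none
10	3	0.33	0.77	FALSE	none
11	2	0.50	0.80	FALSE	none
12	1	1	1	FALSE	none
13	12	0.08	0.38	FALSE	deltran
14	1	1	1	FALSE	none
15	8	0.50	0.77	TRUE	acctran
16	4	0.25	0.75	FALSE	acctran
17	7	0.28	0.61	FALSE	none
18	11	0.18	0.55	FALSE	none
19	1	1	1	FALSE	none
20	9	0.11	0.55	FALSE	none
21	2	0.50	0.66	FALSE	none
22	2	0.50	0.80	FALSE	none
23	2	0.50	0.50	FALSE	deltran
24	4	0.25	0.62	FALSE	none
25	1	1	1	FALSE	none
26	1	1	1	FALSE	none
27	2	1	1	FALSE	none
28	4	0.50	0.71	TRUE	none
29	9	0.22	0.65	TRUE	none
30	1	1	1	FALSE	none
31	2	0.50	0.50	FALSE	acctran
32	6	0.16	0.68	FALSE	deltran
33	4	0.25	0.57	FALSE	none
34	7	0.28	0.54	TRUE	none
35	1	1	1	FALSE	none
36	1	1	1	FALSE	none
37	2	0.50	0.50	FALSE	none
38	10	0.40	0.76	FALSE	none
39	4	0.25	0.81	FALSE	none
40	2	0.50	0.90	FALSE	none
41	2	1	1	FALSE	deltran
42	5	0.40	0.78	FALSE	none
43	1	1	1	FALSE	none
44	4	0.25	0.62	FALSE	deltran
45	2	0.50	0.50	FALSE	none
46	1	1	1	FALSE	none
47	5	0.20	0.42	FALSE	acctran
48	2	0.50	0.50	FALSE	none
49	2	0.50	0.50	FALSE	none
50	2	0.50	0.50	FALSE	none
51	3	0.66	0.83	FALSE	none
52	5	0.20	0.71	FALSE	none
53	5	0.20	0.78	FALSE	none
54	7	0.14	0.57	FALSE	deltran
55	1	1	1	FALSE	none
56	1	1	1	FALSE	none
57	1	1	1	FALSE	none
58	2	1	1	FALSE	none
59	1	1	1	FALSE	none
60	2	0.50	0.66	FALSE	none
61	2	0.50	0.88	FALSE	none
62	2	0.50	0.80	FALSE	none
63	4	0.25	0.57	FALSE	none
64	2	1	1	FALSE	deltran
65	7	0.14	0.50	FALSE	none
66	1	1	1	FALSE	none
67	2	1	1	FALSE	none
68	1	1	1	FALSE	none
69	4	0.25	0.40	FALSE	none
70	3	0.33	0.66	FALSE	acctran
71	6	0.16	0.28	FALSE	deltran
72	5	0.40	0.66	FALSE	none
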