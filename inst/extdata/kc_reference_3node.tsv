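# Reference complexity values for the 13 canonical 3-node patterns.
# KC: block-decomposition Kolmogorov-complexity estimates (bits) obtained
# from the Online Algorithmic Complexity Calculator (CTM/BDM tables) for
# the row-major 9-bit adjacency strings; cc_rank / kc_rank are the
# ascending minimum ranks of CC and KC over the 13 patterns.
id	cc	kc	cc_rank	kc_rank
6	3	23.34	11	1
12	1	23.83	3	3
14	2	24.30	8	6
36	1	23.55	3	2
38	2	24.87	8	8
46	3	25.50	11	13
74	0	23.85	1	4
78	1	25.00	3	9
98	0	24.82	1	7
102	1	25.01	3	10
108	1	25.11	3	11
110	2	25.25	8	12
238	3	24.14	11	5
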