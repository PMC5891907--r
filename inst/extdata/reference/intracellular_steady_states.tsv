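# Reference intracellular steady states over the six (DAMPs, M2) input
# combinations, with equal basin shares (1/6, truncated to two decimals).
DAMPs	M2	ROS	CCL2	TRIF	CD13	IRF3	IFNb	MyD88	pIRAK	NFkB	basin
0	0	0	0	0	0	0	0	0	0	0	16.66%
0	1	0	0	0	0	0	0	0	0	0	16.66%
1	0	0	1	1	1	1	1	1	1	1	16.66%
1	1	0	0	1	1	1	1	1	1	0	16.66%
2	0	1	2	2	1	2	2	2	2	2	16.66%
2	1	1	2	2	1	2	2	2	2	2	16.66%
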