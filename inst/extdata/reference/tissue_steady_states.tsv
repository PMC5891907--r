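# Reference tissue-scale steady states over all 216 configurations, ordered by
# basin size (percentages truncated to two decimals).
DAMPs	M1	M2	Injury	ROS	CCL2	basin
0	0	0	0	0	0	92.59%
2	2	0	1	1	2	5.55%
2	2	0	0	1	2	1.85%
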