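# Starting contexts for the in-silico knockout panel: the clamped node
# ("none" for wild type; the IRAK knockout clamps pIRAK, the model's only IRAK
# species), the starting DAMP level, and the M1/M2 levels where the underlying
# in-vivo studies determined them (NA = enumerate all six completions).
genotype	clamp_node	damps	m1	m2
WT	none	2	1	1
MyD88	MyD88	1	NA	NA
IRAK	pIRAK	1	NA	NA
CCL2	CCL2	1	NA	NA
TRIF	TRIF	1	NA	NA
CD13	CD13	2	1	1
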