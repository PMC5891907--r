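# Reference knockout-panel outcomes: percent of starting completions whose
# trajectory resolves (all-zero tissue fixed point) vs fails to resolve,
# truncated to integer percent.
genotype	resolved_pct	unresolved_pct
WT	100%	0%
MyD88	66%	33%
IRAK	66%	33%
CCL2	66%	33%
TRIF	100%	0%
CD13	100%	0%
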