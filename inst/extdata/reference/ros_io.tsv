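# Reference transition table feeding intracellular steady-state ROS back to
# the tissue scale; M2-independent in the unperturbed model.
DAMPs	ROS
0	0
1	0
2	1
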