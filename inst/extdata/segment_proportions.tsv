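segment	length_frac	mass_frac	com_frac	rog_frac
HAT	0.470	0.678	0.450	0.496
upper_leg	0.245	0.100	0.433	0.323
lower_leg	0.246	0.0465	0.433	0.302
foot	0.152	0.0145	0.500	0.475
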