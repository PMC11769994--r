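name	side	pcsa	lopt	pennation	tendon_slack	ft_frac	path
ILIA	R	30	0.102	0.14	NA	0.5	HAT:0.050:0.020;HAT:0.060:-0.010;upper_leg:0.020:-0.130
GMAXI	R	37	0.142	0.00	NA	0.5	HAT:-0.060:0.030;upper_leg:-0.015:-0.120
HAM	R	60	0.109	0.26	NA	0.5	HAT:-0.070:-0.020;lower_leg:-0.025:-0.050
RECTF	R	25	0.084	0.09	NA	0.5	HAT:0.045:-0.020;upper_leg:0.045:-0.380;lower_leg:0.035:-0.070
VASTI	R	140	0.087	0.07	NA	0.5	upper_leg:0.025:-0.150;upper_leg:0.045:-0.380;lower_leg:0.035:-0.070
BFES	R	12	0.173	0.40	NA	0.5	upper_leg:-0.020:-0.250;lower_leg:-0.028:-0.060
GAMS	R	50	0.055	0.30	NA	0.5	upper_leg:-0.022:-0.390;foot:-0.062:-0.020
SOLEU	R	110	0.055	0.44	NA	0.5	lower_leg:-0.025:-0.150;foot:-0.062:-0.020
TIBAN	R	25	0.098	0.09	NA	0.5	lower_leg:0.027:-0.150;lower_leg:0.030:-0.390;foot:0.110:-0.010
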