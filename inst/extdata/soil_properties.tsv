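# Example per-treatment soil property means from a four-level phosphorus-addition
# field trial (CK = no P; P60/P120/P180 = 60/120/180 kg ha-1). Units: soil_water %,
# soc and tn and tp g kg-1, ap mg kg-1, ph unitless.
property	CK	P60	P120	P180
soil_water	7.75	8.04	7.69	7.89
soc	11.01	11.30	11.60	11.67
tn	0.78	0.80	0.83	0.79
tp	0.82	0.90	0.94	0.98
ap	4.07	5.57	6.05	6.21
ph	8.31	8.29	8.27	8.24
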