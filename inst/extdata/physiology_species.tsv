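# Species-level reference physiology. Units: kg, L/h (plasma), L.
species	body_weight	hematocrit	Q_cardiac	GFR	V_venous	V_arterial	V_lymph
mouse	0.025	0.45	0.46	0.0168	0.00045	3e-04	0.00025
monkey	3	0.4	14.3	0.125	0.048	0.032	0.012
human	73	0.45	172	6.6	1.8	1.2	0.3
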