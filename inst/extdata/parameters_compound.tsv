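# Compound-specific model parameters. species "all" means the value is
# shared across mouse/monkey/human (bioavailability and tissue endosomal
# recycling are compound properties); k_DR is compound- and species-specific
# and NA marks combinations for which no estimate exists (no reference PD
# data). F is stored as a fraction. MW and r_hyd are documented assumptions
# shared by the hairpin-loop-stabilized conjugates.
compound	param	species	unit	value	provenance
siRNA-1	F	all	-	0.47	table3
siRNA-2	F	all	-	0.22	table3
siRNA-3	F	all	-	0.22	table3
siRNA-1	k_recycle_tissue	all	1/min	3.23e-5	table3
siRNA-2	k_recycle_tissue	all	1/min	3.49e-4	table3
siRNA-3	k_recycle_tissue	all	1/min	3.23e-5	table3
siRNA-1	k_DR	mouse	1/h	9.72e-3	table3
siRNA-1	k_DR	monkey	1/h	8.02e-3	table3
siRNA-1	k_DR	human	1/h	NA	table3
siRNA-2	k_DR	mouse	1/h	NA	table3
siRNA-2	k_DR	monkey	1/h	5.28e-3	table3
siRNA-2	k_DR	human	1/h	4.17e-4	table3
siRNA-3	k_DR	mouse	1/h	NA	table3
siRNA-3	k_DR	monkey	1/h	1.94e-3	table3
siRNA-3	k_DR	human	1/h	2.02e-4	table3
siRNA-1	MW	all	g/mol	16000	default
siRNA-2	MW	all	g/mol	16000	default
siRNA-3	MW	all	g/mol	16000	default
siRNA-1	r_hyd	all	nm	3.0	default
siRNA-2	r_hyd	all	nm	3.0	default
siRNA-3	r_hyd	all	nm	3.0	default
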