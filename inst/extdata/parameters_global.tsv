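# Global and species-specific PBPK-PD model parameters (canonical set).
# k_RNase is treated as a second-order constant multiplying the local RNase
# abundance (unit 1/(umol/L)/h). k_endosome_std is the standard-individual
# (mouse) value; monkey/human values are derived by allometric scaling with
# exponent -0.25. RNase_plasma is a package default (abundance in central
# plasma is not an optimized quantity); MW and r_hyd are documented
# assumptions overridable per compound.
param	unit	mouse	monkey	human	provenance
ka	1/h	0.84	4.57	7.73	table2
P_liver	cm/min	0.02	3.05e-3	1.21e-4	table2
fu	-	1.0	1.0	1.0	table2
k_uptake_liver	1/min	0.29	0.29	0.29	table2
k_recycle_liver	1/min	1.33e-3	8.22e-4	4.27e-5	table2
k_uptake_kidney	1/min	24.98	24.98	24.98	table2
k_recycle_kidney	1/min	3.90e-4	3.90e-4	3.90e-4	table2
k_uptake_gonads	1/min	1.48	1.48	1.48	table2
k_uptake_lung	1/min	0.06	0.06	0.06	table2
k_uptake_heart	1/min	0.39	0.39	0.39	table2
k_uptake_spleen	1/min	0.17	0.17	0.17	table2
k_uptake_generic	1/min	0.29	0.29	0.29	table2
k_RNase	1/(umol/L)/h	1.21e-4	1.21e-4	1.21e-4	table2
RNase_kidney	umol/L	1.17	1.17	1.17	table2
RNase_remaining	umol/L	2.75e-2	2.75e-2	2.75e-2	table2
RNase_plasma	umol/L	2.75e-2	2.75e-2	2.75e-2	default
R_tot	umol/L	5.23	2.46	2.46	table2
k_on	L/nmol/h	0.53	0.53	0.53	table2
k_off	1/h	1.53	1.53	1.53	table2
k_deg_R	1/h	1.53	1.53	1.53	table2
k_deg	1/h	1.52	1.52	1.52	table2
k_int	1/h	5.14	5.14	5.14	table2
k_cle	1/h	1.32	1.32	1.32	table2
k_rec	1/h	13.8	13.8	13.8	table2
k_endosome_std	1/h	5.0e-3	5.0e-3	5.0e-3	table2
f_escape	-	0.01	0.01	0.01	table2
k_deg_C	1/h	0.1	0.1	0.1	table2
RISC_tot	umol/L	3e-4	3e-4	3e-4	table2
k_onRISC	L/nmol/h	2.73e-4	2.73e-4	1.68e-5	table2
k_offRISC	1/h	1e-7	1e-7	1e-7	table2
S_max	-	58.84	58.84	58.84	table2
SC_50	nmol/L	3.52	3.52	3.52	table2
k_deg_mRNA	1/h	0.06	0.06	0.06	table2
k_deg_protein	1/h	0.05	0.05	0.05	table2
gamma	-	1.5	1.5	1.5	table2
MW	g/mol	16000	16000	16000	default
r_hyd	nm	3.0	3.0	3.0	default
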