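# Reference mouse physiology (body weight 0.025 kg).
# Units: volumes L, plasma/lymph flows L/h, capillary surface cm^2.
# Compiled reference values from open physiology compendia; liver Q_plasma
# is the hepatic-arterial inflow (portal inflow from spleen/gut/pancreas/
# stomach is added by the circulation topology).
organ	V_vascular	V_interstitial	V_intracellular	V_endosomal	Q_plasma	L_lymph	S_cap
liver	0.000158125	0.000224125	0.000991169	1.58125e-06	0.0092	1.84e-05	343.75
kidney	4.4625e-05	8.5e-05	0.000294929	4.4625e-07	0.04186	8.372e-05	63.75
lung	2.5375e-05	3.325e-05	0.000116121	2.5375e-07	0.460922	0.000921844	17.5
heart	1.25e-05	1.25e-05	9.9875e-05	1.25e-07	0.03036	6.072e-05	12.5
spleen	1.925e-05	1.3125e-05	5.49325e-05	1.925e-07	0.00506	1.012e-05	13.125
gonads	5e-06	2e-05	7.495e-05	5e-08	0.00092	1.84e-06	7
brain	1.5725e-05	7.225e-05	0.000336868	1.5725e-07	0.01518	3.036e-06	42.5
muscle	0.0002496	0.001152	0.0081959	2.496e-06	0.07314	0.00014628	672
skin	0.000185625	0.0012375	0.00270002	1.85625e-06	0.02668	5.336e-05	288.75
adipose	1.75e-05	0.00023625	0.00149608	1.75e-07	0.023	4.6e-05	122.5
bone	0.000109675	0.0002675	0.00229673	1.09675e-06	0.0506	0.0001012	107
gut	3.465e-05	0.0001575	0.000857504	3.465e-07	0.0552	0.0001104	105
pancreas	1.2e-05	1.8e-05	0.00011988	1.2e-07	0.00322	6.44e-06	15
stomach	4.8e-06	1.5e-05	0.000130152	4.8e-08	0.00414	8.28e-06	10.5
carcass	4e-05	1e-04	0.0008596	4e-07	0.12144	0.00024288	40
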