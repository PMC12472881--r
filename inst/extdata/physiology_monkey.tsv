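# Reference monkey physiology (body weight 3 kg).
# Units: volumes L, plasma/lymph flows L/h, capillary surface cm^2.
# Compiled reference values from open physiology compendia; liver Q_plasma
# is the hepatic-arterial inflow (portal inflow from spleen/gut/pancreas/
# stomach is added by the circulation topology).
organ	V_vascular	V_interstitial	V_intracellular	V_endosomal	Q_plasma	L_lymph	S_cap
liver	0.01035	0.01467	0.0648765	0.0001035	0.5005	0.001001	22500
kidney	0.0017325	0.0033	0.0114502	1.7325e-05	1.716	0.003432	2475
lung	0.00348	0.00456	0.0159252	3.48e-05	14.3287	0.0286573	2400
heart	0.0015	0.0015	0.011985	1.5e-05	0.715	0.00143	1500
spleen	0.00165	0.001125	0.0047085	1.65e-05	0.2145	0.000429	1125
gonads	3e-04	0.0012	0.004497	3e-06	0.0429	8.58e-05	420
brain	0.002442	0.01122	0.0523136	2.442e-05	1.001	0.0002002	6600
muscle	0.0312	0.144	1.02449	0.000312	1.859	0.003718	84000
skin	0.0135	0.09	0.196365	0.000135	0.858	0.001716	21000
adipose	0.003	0.0405	0.25647	3e-05	0.572	0.001144	21000
bone	0.0123	0.03	0.257577	0.000123	1.144	0.002288	12000
gut	0.004455	0.02025	0.11025	4.455e-05	2.002	0.004004	13500
pancreas	0.00048	0.00072	0.0047952	4.8e-06	0.143	0.000286	600
stomach	0.000384	0.0012	0.0104122	3.84e-06	0.143	0.000286	840
carcass	0.006	0.015	0.12894	6e-05	3.3891	0.0067782	6000
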