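# Reference human physiology (body weight 73 kg).
# Units: volumes L, plasma/lymph flows L/h, capillary surface cm^2.
# Compiled reference values from open physiology compendia; liver Q_plasma
# is the hepatic-arterial inflow (portal inflow from spleen/gut/pancreas/
# stomach is added by the circulation topology).
organ	V_vascular	V_interstitial	V_intracellular	V_endosomal	Q_plasma	L_lymph	S_cap
liver	0.21827	0.309374	1.36817	0.0021827	11.18	0.02236	474500
kidney	0.033726	0.06424	0.222897	0.00033726	32.68	0.06536	48180
lung	0.080446	0.105412	0.368138	0.00080446	172.345	0.344689	55480
heart	0.03431	0.03431	0.274137	0.0003431	6.88	0.01376	34310
spleen	0.041756	0.02847	0.119156	0.00041756	5.16	0.01032	28470
gonads	0.001825	0.0073	0.0273568	1.825e-05	0.086	0.000172	2555
brain	0.05402	0.2482	1.15724	0.0005402	19.608	0.0039216	146000
muscle	0.7592	3.504	24.9292	0.007592	29.24	0.05848	2044000
skin	0.121874	0.81249	1.77272	0.00121873	8.6	0.0172	189581
adipose	0.15549	2.09912	13.2928	0.0015549	8.6	0.0172	1088430
bone	0.256201	0.62488	5.36516	0.00256201	8.6	0.0172	249952
gut	0.0411939	0.187245	1.01945	0.000411939	27.52	0.05504	124830
pancreas	0.008176	0.012264	0.0816782	8.176e-05	1.72	0.00344	10220
stomach	0.0049056	0.01533	0.133015	4.9056e-05	1.72	0.00344	10731
carcass	0.146	0.365	3.13754	0.00146	10.406	0.020812	146000
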