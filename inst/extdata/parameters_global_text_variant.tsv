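# Alternate species-specific values quoted in the results narrative where
# they differ from the canonical parameter summary table. Values are stored
# in the canonical unit of each parameter (k_recycle_liver entries were
# quoted per hour and are converted to 1/min here).
param	species	value
ka	monkey	4.22
P_liver	monkey	1.56e-3
k_recycle_liver	monkey	3.8333e-7
ka	human	7.18
P_liver	human	1.21e-5
k_recycle_liver	human	7.1167e-7
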