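#type=freqs
#motif_id=ECFtoy_minus35
0.05	0.05	0.85	0.85	0.05	0.05	0.05
0.05	0.05	0.05	0.05	0.85	0.05	0.05
0.85	0.85	0.05	0.05	0.05	0.05	0.05
0.05	0.05	0.05	0.05	0.05	0.85	0.85
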