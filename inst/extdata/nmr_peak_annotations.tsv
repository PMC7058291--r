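ppm	metabolite
0.86	lipoprotein_CH3_VLDL_LDL
0.95	leucine
1.03	valine
1.26	lipoprotein_CH2
1.33	lactate
1.48	alanine
2.04	GlycA
2.22	acetone
2.41	glutamine
3.04	creatinine
3.40	glucose
3.70	glucose
5.23	glucose_anomeric
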