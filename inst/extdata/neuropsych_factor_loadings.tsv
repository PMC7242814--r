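test	speed	memory	crystallized	fluency
cvlt_composite	-0.19	0.84	0.08	-0.15
cvlt_recognition_hits	-0.20	0.42	0.23	-0.64
cvlt_recognition_fa	0.21	-0.69	0.26	-0.17
logical_memory_composite	0.10	0.67	0.18	0.02
trails_a	0.91	-0.09	-0.05	-0.14
trails_b	0.85	-0.09	-0.28	0.08
sdmt	-0.59	0.40	0.08	0.30
digit_span	-0.16	0.01	0.80	-0.08
category_fluency	-0.34	0.23	0.14	0.63
fas	-0.12	0.06	0.46	0.57
wtar	-0.12	0.12	0.79	0.21
ravens	-0.33	0.48	0.10	0.05
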