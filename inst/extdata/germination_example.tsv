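genotype	condition	rep	germinated	total
Col0	water	1	78	80
Col0	water	2	76	80
Col0	water	3	79	80
Col0	NaCl150	1	42	80
Col0	NaCl150	2	39	80
Col0	NaCl150	3	45	80
amiRNA	water	1	77	80
amiRNA	water	2	79	80
amiRNA	water	3	78	80
amiRNA	NaCl150	1	61	80
amiRNA	NaCl150	2	58	80
amiRNA	NaCl150	3	63	80
OE	water	1	78	80
OE	water	2	77	80
OE	water	3	76	80
OE	NaCl150	1	18	80
OE	NaCl150	2	22	80
OE	NaCl150	3	15	80
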