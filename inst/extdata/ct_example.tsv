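gene	group	bio_rep	tech_rep	ct
TdTZF1A	ctrl_0h	1	1	24.12
TdTZF1A	ctrl_0h	1	2	24.05
TdTZF1A	ctrl_0h	1	3	24.21
TdTZF1A	ctrl_0h	2	1	24.33
TdTZF1A	ctrl_0h	2	2	24.18
TdTZF1A	ctrl_0h	2	3	24.27
TdTZF1A	ctrl_0h	3	1	23.98
TdTZF1A	ctrl_0h	3	2	24.10
TdTZF1A	ctrl_0h	3	3	24.02
TdTZF1A	nacl_3h	1	1	22.41
TdTZF1A	nacl_3h	1	2	22.55
TdTZF1A	nacl_3h	1	3	22.47
TdTZF1A	nacl_3h	2	1	22.61
TdTZF1A	nacl_3h	2	2	22.50
TdTZF1A	nacl_3h	2	3	22.39
TdTZF1A	nacl_3h	3	1	22.72
TdTZF1A	nacl_3h	3	2	22.66
TdTZF1A	nacl_3h	3	3	22.58
polyubiquitin	ctrl_0h	1	1	18.02
polyubiquitin	ctrl_0h	1	2	18.11
polyubiquitin	ctrl_0h	1	3	17.95
polyubiquitin	ctrl_0h	2	1	18.20
polyubiquitin	ctrl_0h	2	2	18.08
polyubiquitin	ctrl_0h	2	3	18.14
polyubiquitin	ctrl_0h	3	1	17.99
polyubiquitin	ctrl_0h	3	2	18.05
polyubiquitin	ctrl_0h	3	3	18.09
polyubiquitin	nacl_3h	1	1	18.15
polyubiquitin	nacl_3h	1	2	18.03
polyubiquitin	nacl_3h	1	3	18.22
polyubiquitin	nacl_3h	2	1	18.00
polyubiquitin	nacl_3h	2	2	18.12
polyubiquitin	nacl_3h	2	3	18.06
polyubiquitin	nacl_3h	3	1	18.18
polyubiquitin	nacl_3h	3	2	18.04
polyubiquitin	nacl_3h	3	3	18.10
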