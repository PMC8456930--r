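mutant	substrate_id	ez	ddg	reported_e	reported_capped	reported_config
Leu145Phe	2F	E	3.65	200	TRUE	S
Leu145Phe	2F	Z	2.33	65	FALSE	R
Leu145Phe	3F	E	2.91	184	FALSE	S
Leu145Phe	3F	Z	0.06	1	FALSE	none
Leu145Phe	4F	E	3.85	200	TRUE	S
Leu145Phe	4F	Z	1.36	11	FALSE	R
3M	2F	E	1.77	22	FALSE	S
3M	2F	Z	0.20	1	FALSE	R
3M	3F	E	1.87	29	FALSE	S
3M	3F	Z	1.00	6	FALSE	S
3M	4F	E	1.54	16	FALSE	S
3M	4F	Z	1.40	11	FALSE	S
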