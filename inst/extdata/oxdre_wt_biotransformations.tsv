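substrate_id	ez	conversion_pct	ee_pct	preferred_config	reported_e	reported_ddg
2F	E	45	96	S	112	2.6
2F	Z	50	65	R	9	1.2
3F	E	48	96	S	146	2.7
3F	Z	52	64	R	9	1.2
4F	E	34	93	S	44	2.1
4F	Z	32	54	R	4	0.7
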