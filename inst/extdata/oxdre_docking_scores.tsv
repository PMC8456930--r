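substrate_id	ez_label	rs_label	delta_g
2F	E	R	-7.30
2F	E	S	-9.17
2F	Z	R	-6.24
2F	Z	S	-4.60
3F	E	R	-7.68
3F	E	S	-9.66
3F	Z	R	-6.28
3F	Z	S	-4.77
4F	E	R	-7.07
4F	E	S	-9.72
4F	Z	R	-5.88
4F	Z	S	-4.96
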