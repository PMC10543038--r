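category	level	n_case	n_control
sex	female	527	312
sex	male	160	127
site	TCH	229	130
site	UNC	235	235
site	UW	223	74
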