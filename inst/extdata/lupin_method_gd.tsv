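unit	population_type	RAPD	ISSR	REMAP	combined
Invasive	invasive	0.322	0.253	0.328	0.294
Feral_MBG	feral	0.234	0.238	0.290	0.248
Minaret	variety	0.205	0.171	0.220	0.194
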