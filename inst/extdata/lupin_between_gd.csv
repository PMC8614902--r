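unit,Kostroma,Smolensk,Moscow,Kaluga,MBG,Minaret
Kostroma,0.000,0.216,0.209,0.231,0.269,0.302
Smolensk,0.216,0.000,0.260,0.258,0.284,0.315
Moscow,0.209,0.260,0.000,0.196,0.198,0.318
Kaluga,0.231,0.258,0.196,0.000,0.230,0.341
MBG,0.269,0.284,0.198,0.230,0.000,0.276
Minaret,0.302,0.315,0.318,0.341,0.276,0.000
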