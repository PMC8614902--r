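unit	population_type	min_gd	max_gd	mean_gd
Moscow	invasive	0.217	0.606	0.398
Peskovka	invasive	0.224	0.678	0.418
Kiev	invasive	0.265	0.622	0.441
Zhitomir_industrial	invasive	0.216	0.640	0.446
Zhitomir_center	invasive	0.248	0.629	0.457
Caucasus	native	0.244	0.739	0.502
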