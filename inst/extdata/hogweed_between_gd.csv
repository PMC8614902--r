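unit,Caucasus,Moscow,Kiev,Zhitomir,Pescovka
Caucasus,0.000,0.614,0.611,0.591,0.569
Moscow,0.614,0.000,0.512,0.530,0.562
Kiev,0.611,0.512,0.000,0.493,0.466
Zhitomir,0.591,0.530,0.493,0.000,0.438
Pescovka,0.569,0.562,0.466,0.438,0.000
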