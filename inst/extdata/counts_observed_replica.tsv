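population	group	n	carriers
IndoEuropean_west	indo_european	900	0
IndoEuropean_central	indo_european	900	0
IndoEuropean_east	indo_european	877	0
Sekler	sekler	95	4
UralSiberian_bashkir	ural_siberian	400	52
UralSiberian_khanty	ural_siberian	300	39
UralSiberian_mansi	ural_siberian	257	33
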