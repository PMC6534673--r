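population	group	n	carriers
indo_european_1	indo_european	1339	0
indo_european_2	indo_european	1338	0
sekler_1	sekler	48	4
sekler_2	sekler	47	5
ural_siberian_1	ural_siberian	479	236
ural_siberian_2	ural_siberian	478	212
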