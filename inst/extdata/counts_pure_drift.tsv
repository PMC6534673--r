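population	group	n	carriers
indo_european_1	indo_european	893	142
indo_european_2	indo_european	892	133
indo_european_3	indo_european	892	120
sekler_1	sekler	32	5
sekler_2	sekler	32	5
sekler_3	sekler	31	1
ural_siberian_1	ural_siberian	319	32
ural_siberian_2	ural_siberian	319	47
ural_siberian_3	ural_siberian	319	35
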