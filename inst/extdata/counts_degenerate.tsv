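population	group	n	carriers
FixedPool	fixed	10	10
Sekler	sekler	95	4
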