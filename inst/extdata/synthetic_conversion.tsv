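organ_signature	SBS2	SBS3	SBS13
Organ.A	1	0	0
Organ.B	0	1	0
Organ.C	0.5	0.5	0
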