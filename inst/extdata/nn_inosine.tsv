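# Approximate nearest-neighbor parameters for stacks containing inosine (I),
# modelled as the universal base paired opposite C. Each I-containing stack is
# the arithmetic mean of the four corresponding standard-base stacks from the
# unified table; swap this file via tm_conditions() to use measured values.
# dh: kcal/mol, ds: cal/(mol K)
stack	dh	ds
AI	-7.825	-21.5
CI	-8.725	-22.7
GI	-8.6	-22.225
TI	-7.95	-22.1
IA	-7.95	-22.1
IC	-8.6	-22.225
IG	-8.725	-22.7
IT	-7.825	-21.5
II	-8.275	-22.13125
init_I	1.2	0.65
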