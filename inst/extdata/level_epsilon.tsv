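level	epsilon	sigma
O	5.6	0.47
I	5	0.47
II	4.5	0.47
III	4	0.47
IV	3.5	0.47
V	3.1	0.47
VI	2.7	0.47
VII	2.3	0.47
VIII	2	0.47
IX	2	0.62
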