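item	community
IU1	IU
IU2	IU
IU3	IU
IU4	IU
IU5	IU
IU6	IU
IU7	IU
IU8	IU
IU9	IU
IU10	IU
IU11	IU
IU12	IU
A1	GAD
A2	GAD
A3	GAD
A4	GAD
A5	GAD
A6	GAD
A7	GAD
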