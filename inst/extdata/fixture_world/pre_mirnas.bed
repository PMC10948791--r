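chrF	20000	20080	preA1	0	+
chrF	20280	20360	preA2	0	+
chrF	31000	31080	preB1	0	+
chrF	41080	41160	preB2	0	+
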