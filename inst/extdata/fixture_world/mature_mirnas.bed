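chrF	20010	20032	matA1a|preA1	0	+
chrF	20058	20080	matA1b|preA1	0	+
chrF	20280	20302	matA2a|preA2	0	+
chrF	20330	20352	matA2b|preA2	0	+
chrF	31010	31032	matB1|preB1	0	+
chrF	41090	41112	matB2|preB2	0	+
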