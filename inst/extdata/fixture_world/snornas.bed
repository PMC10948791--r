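chrF	5100	5180	S1	0	+
chrF	7700	7800	S2	0	+
chrF	9400	9500	S3	0	-
chrF	13100	13180	S4	0	+
chrF	17200	17300	S5	0	+
chrF	18500	18580	S6	0	+
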