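chrF	1000	1500	I1	0	+
chrF	2000	2600	I2	0	-
chrF	3000	3400	I3	0	+
chrF	5000	5800	I4	0	+
chrF	7000	7900	I5	0	+
chrF	9000	9600	I6	0	-
chrF	11000	11200	I7	0	+
chrF	12000	12500	I8	0	-
chrF	13000	13800	I9	0	+
chrF	15000	15600	I10	0	+
chrF	16000	16400	I11	0	-
chrF	17000	17700	I12	0	+
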