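chrF	1000	1500	c01	0	+
chrF	2000	2600	c02	0	-
chrF	1000	1450	c03	0	+
chrF	1001	1500	c04	0	+
chrF	3000	3400	c05	0	-
chrF	3000	3400	c06	0	+
chrF	5100	5795	c07	0	+
chrF	5100	5790	c08	0	+
chrF	5100	5789	c09	0	+
chrF	5100	5180	c10	0	+
chrF	7004	7800	c11	0	+
chrF	6989	7800	c12	0	+
chrF	9004	9500	c13	0	-
chrF	13100	13790	c14	0	+
chrF	13100	13788	c15	0	+
chrF	17000	17700	c16	0	+
chrF	17200	17690	c17	0	+
chrF	18500	18580	c18	0	+
chrF	20058	20302	c19	0	+
chrF	20060	20300	c20	0	+
chrF	20010	20032	c21	0	+
chrF	20000	20080	c22	0	+
chrF	20100	20250	c23	0	+
chrF	20000	20360	c24	0	-
chrF	31000	41160	c25	0	+
chrF	45050	45200	c26	0	+
chrF	45050	45200	c27	0	-
chrF	46000	46070	c28	0	-
chrF	2000	2600	c29	0	+
chrF	50000	50400	c30	0	+
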