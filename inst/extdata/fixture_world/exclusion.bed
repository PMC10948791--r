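chrF	45000	45150	rRNA1	0	+
chrF	46000	46070	tRNA1	0	-
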