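name	slirna	snotron	misrna	excluded
c01	True	False	False	False
c02	True	False	False	False
c03	False	False	False	False
c04	False	False	False	False
c05	False	False	False	False
c06	True	False	False	False
c07	False	True	False	False
c08	False	True	False	False
c09	False	False	False	False
c10	False	False	False	False
c11	False	True	False	False
c12	False	False	False	False
c13	False	True	False	False
c14	False	True	False	False
c15	False	False	False	False
c16	True	False	False	False
c17	False	True	False	False
c18	False	False	False	False
c19	False	False	True	False
c20	False	False	True	False
c21	False	False	False	False
c22	False	False	False	False
c23	False	False	True	False
c24	False	False	False	False
c25	False	False	False	False
c26	False	False	False	True
c27	False	False	False	False
c28	False	False	False	True
c29	False	False	False	False
c30	False	False	False	False
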