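source	target
G01	G04
G05	G04
G05	G02
G03	G01
G01	G03
G03	G04
G02	G05
G05	G03
G03	G02
G04	G02
G03	G05
G02	G03
G01	G05
G06	G09
G09	G07
G09	G06
G07	G09
G10	G09
G08	G07
G09	G10
G09	G08
G06	G08
G10	G08
G06	G10
G08	G06
G08	G10
G12	G11
G11	G15
G15	G13
G13	G12
G11	G12
G14	G12
G12	G13
G12	G15
G15	G12
G11	G14
G11	G13
G14	G11
G13	G15
G01	G06
G07	G12
G13	G02
G05	G11
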