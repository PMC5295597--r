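gonad_id	n_embryonic_clones	gfp_pos_cells	bgal_pos_among_gfp
G01	1	8	8
G02	1	8	8
G03	1	8	8
G04	1	8	0
G05	1	8	0
G06	1	8	0
G07	1	8	0
G08	1	8	0
G09	1	8	0
G10	1	8	0
G11	2	16	16
G12	2	16	16
G13	2	16	0
G14	2	16	0
G15	2	16	0
G16	2	16	0
G17	2	16	8
G18	2	16	8
G19	2	16	8
G20	2	16	8
G21	2	16	8
G22	2	14	5
G23	2	10	2
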