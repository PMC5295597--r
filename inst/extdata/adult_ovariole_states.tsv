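ovariole_id	chamber	gfp	bgal
OV01	1	1	1
OV01	2	0	0
OV02	1	1	1
OV02	2	0	0
OV03	1	1	1
OV03	2	0	0
OV04	1	1	1
OV04	2	0	0
OV05	1	1	1
OV05	2	0	0
OV06	1	1	1
OV06	2	0	0
OV07	1	1	1
OV07	2	0	0
OV08	1	1	1
OV08	2	0	0
OV09	1	1	1
OV09	2	0	0
OV10	1	1	1
OV10	2	0	0
OV11	1	1	1
OV11	2	0	0
OV12	1	1	1
OV12	2	0	0
OV13	1	1	1
OV13	2	0	0
OV14	1	1	1
OV14	2	0	0
OV15	1	1	1
OV15	2	0	0
OV16	1	1	1
OV16	2	0	0
OV17	1	1	1
OV17	2	0	0
OV18	1	1	1
OV18	2	0	0
OV19	1	1	1
OV19	2	0	0
OV20	1	1	1
OV20	2	0	0
OV21	1	1	1
OV21	2	0	0
OV22	1	1	1
OV22	2	0	0
OV23	1	1	1
OV23	2	0	0
OV24	1	1	1
OV24	2	0	0
OV25	1	1	1
OV25	2	0	0
OV26	1	1	1
OV26	2	0	0
OV27	1	1	1
OV27	2	0	0
OV28	1	1	1
OV28	2	0	0
OV29	1	1	0
OV29	2	0	1
OV30	1	1	0
OV30	2	0	1
OV31	1	1	0
OV31	2	0	1
OV32	1	1	0
OV32	2	0	1
OV33	1	1	0
OV33	2	0	1
OV34	1	1	0
OV34	2	0	1
OV35	1	1	0
OV35	2	0	1
OV36	1	1	0
OV36	2	0	1
OV37	1	1	0
OV37	2	0	1
OV38	1	1	0
OV38	2	0	1
OV39	1	1	0
OV39	2	0	1
OV40	1	1	1
OV40	2	0	0
OV40	3	1	0
OV41	1	1	1
OV41	2	0	0
OV41	3	1	0
OV42	1	1	1
OV42	2	0	0
OV42	3	1	0
OV43	1	1	1
OV43	2	0	0
OV43	3	1	0
OV44	1	1	1
OV44	2	0	0
OV44	3	1	0
OV45	1	1	1
OV45	2	0	0
OV45	3	1	0
OV46	1	1	1
OV46	2	0	0
OV46	3	1	0
OV47	1	1	1
OV47	2	0	0
OV47	3	1	0
OV48	1	1	1
OV48	2	0	0
OV48	3	1	0
OV49	1	1	1
OV49	2	0	0
OV49	3	1	0
OV50	1	1	1
OV50	2	0	0
OV50	3	1	0
OV51	1	1	1
OV51	2	0	0
OV51	3	1	0
OV52	1	1	1
OV52	2	0	0
OV52	3	1	0
OV53	1	1	1
OV53	2	0	0
OV53	3	1	0
OV54	1	1	1
OV54	2	0	0
OV54	3	1	0
OV55	1	1	1
OV55	2	0	0
OV55	3	1	0
OV56	1	1	1
OV56	2	0	0
OV56	3	1	0
OV57	1	1	1
OV57	2	0	0
OV57	3	1	0
OV58	1	1	1
OV58	2	0	0
OV58	3	1	0
OV59	1	1	1
OV59	2	0	0
OV59	3	1	0
OV60	1	1	1
OV60	2	0	0
OV60	3	1	0
OV61	1	1	1
OV61	2	0	0
OV61	3	1	0
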