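gene	weight
HYP01	1
HYP02	1
HYP03	1
HYP04	1
HYP05	1
HYP06	1
HYP07	1
HYP08	1
HYP09	1
HYP10	1
HYP11	1
HYP12	1
HYP13	1
HYP14	1
HYP15	1
HYP16	1
HYP17	1
HYP18	1
HYP19	1
HYP20	1
HYP21	1
HYP22	1
HYP23	1
HYP24	1
HYP25	1
HYP26	1
HYP27	1
HYP28	1
HYP29	1
HYP30	1
HYP31	1
HYP32	1
HYP33	1
HYP34	1
HYP35	1
HYP36	1
HYP37	1
HYP38	1
HYP39	1
HYP40	1
HYP41	1
HYP42	1
HYP43	1
HYP44	1
HYP45	1
HYP46	1
HYP47	1
HYP48	1
HYP49	1
HYP50	1
HYP51	1
HYP52	1
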