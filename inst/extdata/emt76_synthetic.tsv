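gene	weight
MES01	1
MES02	1
MES03	1
MES04	1
MES05	1
MES06	1
MES07	1
MES08	1
MES09	1
MES10	1
MES11	1
MES12	1
MES13	1
MES14	1
MES15	1
MES16	1
MES17	1
MES18	1
MES19	1
MES20	1
MES21	1
MES22	1
MES23	1
MES24	1
MES25	1
MES26	1
MES27	1
MES28	1
MES29	1
MES30	1
MES31	1
MES32	1
MES33	1
MES34	1
MES35	1
MES36	1
MES37	1
MES38	1
EPI01	-1
EPI02	-1
EPI03	-1
EPI04	-1
EPI05	-1
EPI06	-1
EPI07	-1
EPI08	-1
EPI09	-1
EPI10	-1
EPI11	-1
EPI12	-1
EPI13	-1
EPI14	-1
EPI15	-1
EPI16	-1
EPI17	-1
EPI18	-1
EPI19	-1
EPI20	-1
EPI21	-1
EPI22	-1
EPI23	-1
EPI24	-1
EPI25	-1
EPI26	-1
EPI27	-1
EPI28	-1
EPI29	-1
EPI30	-1
EPI31	-1
EPI32	-1
EPI33	-1
EPI34	-1
EPI35	-1
EPI36	-1
EPI37	-1
EPI38	-1
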