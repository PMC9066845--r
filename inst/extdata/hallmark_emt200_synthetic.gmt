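HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION_SYNTHETIC	synthetic stand-in for the 200-gene Hallmark EMT pathway set	MES01	MES02	MES03	MES04	MES05	MES06	MES07	MES08	MES09	MES10	MES11	MES12	MES13	MES14	MES15	MES16	MES17	MES18	MES19	MES20	MES21	MES22	MES23	MES24	MES25	MES26	MES27	MES28	MES29	MES30	MES31	MES32	MES33	MES34	MES35	MES36	MES37	MES38	EPI01	EPI02	EPI03	EPI04	EPI05	EPI06	EPI07	EPI08	EPI09	EPI10	EPI11	EPI12	EPI13	EPI14	EPI15	EPI16	EPI17	EPI18	EPI19	EPI20	EPI21	EPI22	EPI23	EPI24	EPI25	EPI26	EPI27	EPI28	EPI29	EPI30	EPI31	EPI32	EPI33	EPI34	EPI35	EPI36	EPI37	EPI38	EMT001	EMT002	EMT003	EMT004	EMT005	EMT006	EMT007	EMT008	EMT009	EMT010	EMT011	EMT012	EMT013	EMT014	EMT015	EMT016	EMT017	EMT018	EMT019	EMT020	EMT021	EMT022	EMT023	EMT024	EMT025	EMT026	EMT027	EMT028	EMT029	EMT030	EMT031	EMT032	EMT033	EMT034	EMT035	EMT036	EMT037	EMT038	EMT039	EMT040	EMT041	EMT042	EMT043	EMT044	EMT045	EMT046	EMT047	EMT048	EMT049	EMT050	EMT051	EMT052	EMT053	EMT054	EMT055	EMT056	EMT057	EMT058	EMT059	EMT060	EMT061	EMT062	EMT063	EMT064	EMT065	EMT066	EMT067	EMT068	EMT069	EMT070	EMT071	EMT072	EMT073	EMT074	EMT075	EMT076	EMT077	EMT078	EMT079	EMT080	EMT081	EMT082	EMT083	EMT084	EMT085	EMT086	EMT087	EMT088	EMT089	EMT090	EMT091	EMT092	EMT093	EMT094	EMT095	EMT096	EMT097	EMT098	EMT099	EMT100	EMT101	EMT102	EMT103	EMT104	EMT105	EMT106	EMT107	EMT108	EMT109	EMT110	EMT111	EMT112	EMT113	EMT114	EMT115	EMT116	EMT117	EMT118	EMT119	EMT120	EMT121	EMT122	EMT123	EMT124
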