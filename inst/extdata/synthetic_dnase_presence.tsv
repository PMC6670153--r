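# synthetic DNase presence matrix: 124 cell types x 10 modules; modules VI and X carried in >80 cell types
cell_type	I	II	III	IV	V	VI	VII	VIII	IX	X
synCT001	0	0	0	0	0	1	1	1	1	0
synCT002	0	0	0	0	0	1	1	1	1	0
synCT003	0	0	0	0	0	1	1	1	1	0
synCT004	0	0	0	0	0	1	0	1	1	0
synCT005	0	0	0	0	0	1	0	1	1	0
synCT006	0	0	0	0	0	1	0	1	1	0
synCT007	0	0	0	0	0	1	0	1	1	1
synCT008	0	0	0	0	0	1	0	1	1	1
synCT009	0	0	0	0	0	1	0	1	1	1
synCT010	0	0	0	0	0	1	0	0	1	1
synCT011	0	0	0	0	0	1	0	0	1	1
synCT012	0	0	0	0	0	1	0	0	1	1
synCT013	0	0	0	0	0	1	0	0	1	1
synCT014	1	0	0	0	0	1	0	0	1	1
synCT015	1	0	0	0	0	1	0	0	1	1
synCT016	1	0	0	0	0	1	0	0	1	1
synCT017	1	0	0	0	0	1	0	0	1	1
synCT018	1	0	0	0	0	1	0	0	1	1
synCT019	1	0	0	0	0	1	0	0	1	1
synCT020	1	0	0	0	0	1	0	0	1	1
synCT021	1	0	0	0	0	1	0	0	1	1
synCT022	1	0	0	0	0	1	0	0	1	1
synCT023	1	0	0	0	0	1	0	0	1	1
synCT024	1	0	0	0	0	1	0	0	1	1
synCT025	1	0	0	0	0	1	0	0	1	1
synCT026	1	0	0	0	0	1	0	0	1	1
synCT027	1	1	0	0	0	1	0	0	1	1
synCT028	1	1	0	0	0	1	0	0	1	1
synCT029	1	1	0	0	0	1	0	0	1	1
synCT030	1	1	0	0	0	1	0	0	1	1
synCT031	1	1	0	0	0	1	0	0	1	1
synCT032	1	1	0	0	0	1	0	0	1	1
synCT033	1	1	0	0	0	1	0	0	1	1
synCT034	1	1	0	0	0	1	0	0	1	1
synCT035	1	1	0	0	0	1	0	0	1	1
synCT036	1	1	0	0	0	1	0	0	1	1
synCT037	1	1	0	0	0	1	0	0	1	1
synCT038	1	1	0	0	0	1	0	0	1	1
synCT039	1	1	0	0	0	1	0	0	1	1
synCT040	1	1	1	0	0	1	0	0	1	1
synCT041	1	1	1	0	0	1	0	0	1	1
synCT042	1	1	1	0	0	1	0	0	1	1
synCT043	1	1	1	0	0	1	0	0	1	1
synCT044	1	1	1	0	0	1	0	0	1	1
synCT045	1	1	1	0	0	1	0	0	1	1
synCT046	1	1	1	0	0	1	0	0	1	1
synCT047	1	1	1	0	0	1	0	0	1	1
synCT048	1	1	1	0	0	1	0	0	1	1
synCT049	1	1	1	0	0	1	0	0	1	1
synCT050	1	1	1	0	0	0	0	0	1	1
synCT051	1	0	1	0	0	0	0	0	1	1
synCT052	0	0	1	0	0	0	0	0	1	1
synCT053	0	0	1	1	0	0	0	0	1	1
synCT054	0	0	1	1	0	0	0	0	1	1
synCT055	0	0	1	1	0	0	0	0	0	1
synCT056	0	0	1	1	0	0	0	0	0	1
synCT057	0	0	1	1	0	0	0	0	0	1
synCT058	0	0	1	1	0	0	0	0	0	1
synCT059	0	0	1	1	0	0	0	0	0	1
synCT060	0	0	1	1	0	0	0	0	0	1
synCT061	0	0	1	1	0	0	0	0	0	1
synCT062	0	0	1	1	0	0	0	0	0	1
synCT063	0	0	1	1	0	0	0	0	0	1
synCT064	0	0	1	1	0	0	0	0	0	1
synCT065	0	0	1	1	0	0	0	0	0	1
synCT066	0	0	1	1	1	0	0	0	0	1
synCT067	0	0	1	1	1	0	0	0	0	1
synCT068	0	0	1	1	1	0	0	0	0	1
synCT069	0	0	1	1	1	0	0	0	0	1
synCT070	0	0	1	1	1	0	0	0	0	1
synCT071	0	0	1	1	1	0	0	0	0	1
synCT072	0	0	1	1	1	0	0	0	0	1
synCT073	0	0	1	1	1	0	0	0	0	1
synCT074	0	0	1	1	1	0	0	0	0	1
synCT075	0	0	1	1	1	0	0	0	0	1
synCT076	0	0	1	1	1	0	0	0	0	1
synCT077	0	0	1	1	1	0	0	0	0	1
synCT078	0	0	1	1	1	0	0	0	0	1
synCT079	0	0	1	1	1	1	0	0	0	1
synCT080	0	0	1	1	1	1	0	0	0	1
synCT081	0	0	1	1	1	1	0	0	0	1
synCT082	0	0	1	1	1	1	0	0	0	1
synCT083	0	0	1	1	1	1	0	0	0	1
synCT084	0	0	1	0	1	1	0	0	0	1
synCT085	0	0	1	0	1	1	0	0	0	1
synCT086	0	0	1	0	1	1	0	0	0	1
synCT087	0	0	1	0	1	1	0	0	0	1
synCT088	0	0	1	0	1	1	0	0	0	1
synCT089	0	0	1	0	1	1	0	0	0	1
synCT090	0	0	1	0	1	1	0	0	0	1
synCT091	0	0	1	0	1	1	0	0	0	1
synCT092	0	0	1	0	1	1	1	0	0	1
synCT093	0	0	1	0	1	1	1	0	0	1
synCT094	0	0	1	0	1	1	1	0	0	1
synCT095	0	0	0	0	1	1	1	0	0	0
synCT096	0	0	0	0	1	1	1	0	0	0
synCT097	0	0	0	0	1	1	1	0	0	0
synCT098	0	0	0	0	1	1	1	0	0	0
synCT099	0	0	0	0	1	1	1	0	0	0
synCT100	0	0	0	0	1	1	1	0	0	0
synCT101	0	0	0	0	1	1	1	0	0	0
synCT102	0	0	0	0	1	1	1	0	0	0
synCT103	0	0	0	0	1	1	1	0	0	0
synCT104	0	0	0	0	1	1	1	0	0	0
synCT105	0	0	0	0	1	1	1	1	0	0
synCT106	0	0	0	0	1	1	1	1	0	0
synCT107	0	0	0	0	1	1	1	1	0	0
synCT108	0	0	0	0	1	1	1	1	0	0
synCT109	0	0	0	0	1	1	1	1	0	0
synCT110	0	0	0	0	1	1	1	1	0	0
synCT111	0	0	0	0	1	1	1	1	0	0
synCT112	0	0	0	0	1	1	1	1	0	0
synCT113	0	0	0	0	0	1	1	1	0	0
synCT114	0	0	0	0	0	1	1	1	0	0
synCT115	0	0	0	0	0	1	1	1	0	0
synCT116	0	0	0	0	0	1	1	1	0	0
synCT117	0	0	0	0	0	1	1	1	0	0
synCT118	0	0	0	0	0	1	1	1	1	0
synCT119	0	0	0	0	0	1	1	1	1	0
synCT120	0	0	0	0	0	1	1	1	1	0
synCT121	0	0	0	0	0	1	1	1	1	0
synCT122	0	0	0	0	0	1	1	1	1	0
synCT123	0	0	0	0	0	1	1	1	1	0
synCT124	0	0	0	0	0	1	1	1	1	0
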