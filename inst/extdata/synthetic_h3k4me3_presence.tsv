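# synthetic H3K4me3 presence matrix: 51 cell types x 10 modules + gene-free control (exactly 1 carrier)
cell_type	I	II	III	IV	V	VI	VII	VIII	IX	X	gene_free_chr1
synCT001	0	0	0	0	0	1	1	0	0	1	0
synCT002	0	0	0	0	0	1	1	0	0	1	0
synCT003	0	0	0	0	0	1	1	0	0	1	0
synCT004	0	0	0	0	0	1	1	0	0	1	0
synCT005	0	0	0	0	0	1	1	0	0	1	0
synCT006	0	0	0	0	0	1	0	1	0	1	0
synCT007	0	0	0	0	0	1	0	1	0	1	0
synCT008	1	0	0	0	0	1	0	1	0	1	0
synCT009	1	0	0	0	0	1	0	1	0	1	0
synCT010	1	0	0	0	0	1	0	1	0	0	0
synCT011	1	0	0	0	0	1	0	0	0	0	0
synCT012	1	0	0	0	0	1	0	0	0	0	0
synCT013	0	0	0	0	0	1	0	0	1	0	0
synCT014	0	0	0	0	0	1	0	0	1	0	0
synCT015	0	1	0	0	0	1	0	0	1	0	0
synCT016	0	1	0	0	0	1	0	0	1	0	0
synCT017	0	1	0	0	0	1	0	0	1	0	1
synCT018	0	0	0	0	0	1	0	0	1	0	0
synCT019	0	0	0	0	0	1	0	0	1	0	0
synCT020	0	0	0	0	0	1	0	0	1	1	0
synCT021	0	0	0	0	0	1	0	0	1	1	0
synCT022	0	0	1	0	0	1	0	0	1	1	0
synCT023	0	0	1	0	0	1	0	0	1	1	0
synCT024	0	0	1	0	0	1	0	0	1	1	0
synCT025	0	0	1	0	0	1	0	0	1	1	0
synCT026	0	0	1	0	0	1	0	0	1	1	0
synCT027	0	0	1	0	0	1	0	0	1	1	0
synCT028	0	0	1	0	0	1	0	0	1	1	0
synCT029	0	0	1	1	0	1	0	0	1	1	0
synCT030	0	0	0	1	0	1	0	0	1	1	0
synCT031	0	0	0	1	0	1	0	0	1	1	0
synCT032	0	0	0	1	0	1	0	0	1	1	0
synCT033	0	0	0	0	0	1	0	0	1	1	0
synCT034	0	0	0	0	0	1	0	0	1	1	0
synCT035	0	0	0	0	0	1	0	0	1	1	0
synCT036	0	0	0	0	1	0	0	0	1	1	0
synCT037	0	0	0	0	1	0	0	0	1	1	0
synCT038	0	0	0	0	1	0	0	0	1	1	0
synCT039	0	0	0	0	1	0	0	0	1	1	0
synCT040	0	0	0	0	1	0	0	0	1	1	0
synCT041	0	0	0	0	1	0	0	0	1	1	0
synCT042	0	0	0	0	0	0	0	0	1	1	0
synCT043	0	0	0	0	0	1	0	0	1	1	0
synCT044	0	0	0	0	0	1	0	0	1	1	0
synCT045	0	0	0	0	0	1	0	0	1	1	0
synCT046	0	0	0	0	0	1	0	0	1	1	0
synCT047	0	0	0	0	0	1	0	0	1	1	0
synCT048	0	0	0	0	0	1	0	0	1	1	0
synCT049	0	0	0	0	0	1	0	0	1	1	0
synCT050	0	0	0	0	0	1	1	0	1	1	0
synCT051	0	0	0	0	0	1	1	0	0	1	0
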