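# synthetic EST coordinate table: 53 records inside the intron-5-like region (28 minus / 25 plus), 4 outside
# the 8 antisense accessions over the BCR2-like interval carry their published ids; all coordinates are synthetic
accession	chrom	start	end	strand
BU689215	chr21	36209145	36209541	+
BU684610	chr21	36209360	36209776	+
AW204843	chr21	36209679	36210212	+
BX111268	chr21	36210029	36210446	+
AI863417	chr21	36210223	36210637	+
AI798118	chr21	36210573	36211109	+
AI810863	chr21	36210887	36211337	+
AA984901	chr21	36211154	36211525	+
SYNP0001	chr21	36209550	36209829	+
SYNP0002	chr21	36215569	36215969	+
SYNP0003	chr21	36218043	36218499	+
SYNP0004	chr21	36216169	36216369	+
SYNP0005	chr21	36213144	36213574	+
SYNP0006	chr21	36212511	36213024	+
SYNP0007	chr21	36206758	36207067	+
SYNP0008	chr21	36215394	36215671	+
SYNP0009	chr21	36214305	36214611	+
SYNP0010	chr21	36219276	36219659	+
SYNP0011	chr21	36201956	36202413	+
SYNP0012	chr21	36208618	36208895	+
SYNP0013	chr21	36205450	36205655	+
SYNP0014	chr21	36204477	36204810	+
SYNP0015	chr21	36210816	36211071	+
SYNP0016	chr21	36220885	36221274	+
SYNP0017	chr21	36216361	36216947	+
SYNM0001	chr21	36222729	36223202	-
SYNM0002	chr21	36216745	36217118	-
SYNM0003	chr21	36220833	36221397	-
SYNM0004	chr21	36214239	36214785	-
SYNM0005	chr21	36218354	36218636	-
SYNM0006	chr21	36202581	36203103	-
SYNM0007	chr21	36214703	36214973	-
SYNM0008	chr21	36205413	36205656	-
SYNM0009	chr21	36222129	36222667	-
SYNM0010	chr21	36201882	36202332	-
SYNM0011	chr21	36203149	36203647	-
SYNM0012	chr21	36209498	36210008	-
SYNM0013	chr21	36210501	36210734	-
SYNM0014	chr21	36202308	36202792	-
SYNM0015	chr21	36207538	36208073	-
SYNM0016	chr21	36218105	36218489	-
SYNM0017	chr21	36205719	36205978	-
SYNM0018	chr21	36209185	36209495	-
SYNM0019	chr21	36205959	36206375	-
SYNM0020	chr21	36217314	36217844	-
SYNM0021	chr21	36216757	36217180	-
SYNM0022	chr21	36202495	36203066	-
SYNM0023	chr21	36201378	36201895	-
SYNM0024	chr21	36200082	36200440	-
SYNM0025	chr21	36216944	36217146	-
SYNM0026	chr21	36222745	36222965	-
SYNM0027	chr21	36215479	36216034	-
SYNM0028	chr21	36209770	36210033	-
SYNOUT01	chr1	50000100	50000600	+
SYNOUT02	chr22	41000100	41000700	-
SYNOUT03	chr21	36150000	36150500	+
SYNOUT04	chr21	36230000	36230400	-
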