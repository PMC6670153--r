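name	chrom	start	end	coordinate_convention
RUNX1_intron5	chr21	36200000	36224800	0-half-open
BCR1	chr21	36218000	36218800	0-half-open
BCR2	chr21	36209000	36213200	0-half-open
BCR3	chr21	36200200	36202300	0-half-open
SNRPD3_TSS_region	chr22	41000000	41010000	0-half-open
gene_free_chr1	chr1	50000000	50025000	0-half-open
M_BCR	chr22	23520000	23527500	0-half-open
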