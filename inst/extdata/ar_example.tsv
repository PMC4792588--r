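# Example androgen receptor (AR) locus splice catalog.
# Coordinates are synthetic (toy genome), 1-based inclusive; the exon/junction
# structure mirrors the curated AR variant architecture: canonical exons 1-8,
# alternative first exon 1a, cryptic exons CE1/CE3/CE4/CE5 and the
# non-canonical 3' terminal exon 9 used by the 6-9 exon-skipping event.
record	id	chrom	start_1based	end_1based	role	label	upstream_exon	downstream_exon	class	candidate_variants	locus_name	strand	reference_junctions	target_event
meta											AR	+	1-2;1a-2	3-CE3
exon	1	chrX	1001	2000	canonical
exon	1a	chrX	5001	5400	alternative_first
exon	2	chrX	8001	8152	canonical
exon	CE4	chrX	9501	9800	cryptic
exon	3	chrX	12001	12117	canonical
exon	CE1	chrX	14001	14300	cryptic
exon	CE3	chrX	16001	16500	cryptic
exon	CE5	chrX	18001	18350	cryptic
exon	4	chrX	21001	21288	canonical
exon	5	chrX	23001	23145	canonical
exon	6	chrX	25001	25131	canonical
exon	7	chrX	27001	27158	canonical
exon	8	chrX	29001	29400	canonical
exon	9	chrX	32001	32600	cryptic
junction						1-2	1	2	canonical
junction						1a-2	1a	2	alternative_first	AR45
junction						2-3	2	3	canonical
junction						3-4	3	4	canonical
junction						4-5	4	5	canonical
junction						5-6	5	6	canonical
junction						6-7	6	7	canonical
junction						7-8	7	8	canonical
junction						2-CE4	2	CE4	cryptic_exon	AR-V3
junction						3-CE1	3	CE1	cryptic_exon	AR-V1;AR-V2;AR-V4
junction						3-CE3	3	CE3	cryptic_exon	AR-V7
junction						3-CE5	3	CE5	cryptic_exon	AR-V9
junction						6-9	6	9	exon_skipping	AR-V13;AR-V15;AR-V18
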