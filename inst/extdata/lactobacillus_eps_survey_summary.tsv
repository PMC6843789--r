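gene	abbreviation	n_proteins	n_families	n_clusters_missing	n_loose_families	printed_proteins_per_family	printed_families_per_loose	printed_singleton_percent	n_clusters_multicopy	printed_mean_copies	printed_mean_families
LytR-transcriptional regulator	epsA	78	8	74	2	9.8	4	12.5	5	2.2	1
Tyrosine kinase modulator	epsB	130	29	25	15	4.4	1.9	37.9	9	2	2
Tyrosine kinase	epsC	125	25	30	10	5	2.5	28	8	2	2
Phosphotyrosine phosphatase	epsD	97	11	49	1	8.8	11	9.1	0	NA	NA
Priming glycosyltransferase	epsE	140	24	10	8	5.8	3	33.3	4	2	1.8
Glycosyltransferase	gt	670	343	0	246	1.9	1.4	66.6	140	4.6	4.3
Flippase	wzx	147	39	18	16	3.8	2.4	46.2	17	2.17	2
Polysaccharide polymerase	wzy	103	50	42	42	2	1.2	73.8	2	2	2
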