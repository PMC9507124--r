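panel	group	yes	n	pct_printed	note
hatch	wild_type	1111	1208	92	reconstructed round-half-up of pct x N
hatch	ci	48	2397	2	reconstructed round-half-up of pct x N
hatch	rescue	1127	1281	88	reconstructed round-half-up of pct x N
hatch	reciprocal	1182	1299	91	reconstructed round-half-up of pct x N
blastula	wild_type	113	117	97	reconstructed round-half-up of pct x N
blastula	ci	45	159	28	reconstructed round-half-up of pct x N
blastula	rescue	57	66	87	reconstructed round-half-up of pct x N
blastula	reciprocal	47	47	100	reconstructed round-half-up of pct x N
live_blastula	wild_type	36	40	91	reconstructed round-half-up of pct x N
live_hatch	wild_type	53	58	92	reconstructed round-half-up of pct x N
live_blastula	ci	56	147	38	reconstructed round-half-up of pct x N
live_hatch	ci	18	110	16	reconstructed round-half-up of pct x N
abnormal_cyc2_9	wild_type	0	64	0	printed count
abnormal_cyc10_11	wild_type	0	13	0	printed count
abnormal_cyc12_14	wild_type	1	58	2	printed count
abnormal_cyc2_9	ci	2	63	3	printed count
abnormal_cyc10_11	ci	26	108	24	printed count
abnormal_cyc12_14	ci	72	190	38	printed count
abnormal_cyc12_14	rescue	7	128	5	printed count
transgene_positive	ci	38	91	42	reconstructed round-half-up of pct x N
egg_to_adult	wild_type	520	548	95	printed count
egg_to_adult	ci	94	137	69	printed count
egg_to_adult	rescue	511	588	87	printed count
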