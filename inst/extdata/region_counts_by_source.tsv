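#source	data_type	n_samples	one_mark	two_mark	three_mark
GEO	tissues	20	483001	NA	NA
GEO	cells	12	458149	NA	NA
GEO	cell_lines	57	986091	NA	NA
ENCODE	tissues	132	3037358	NA	NA
ENCODE	cells	185	26714405	NA	NA
ENCODE	cell_lines	135	9676827	NA	NA
EMBL	tissues	6	77562	NA	NA
EMBL	cells	6	134650	NA	NA
EMBL	cell_lines	25	395802	NA	NA
GEO_ENCODE_EMBL	tissues	NA	NA	64589	NA
GEO_ENCODE_EMBL	cells	NA	NA	395643	1595
GEO_ENCODE_EMBL	cell_lines	NA	NA	412408	1663
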