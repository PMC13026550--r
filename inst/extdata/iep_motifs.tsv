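name	type	pattern	max_mismatch	min_copies	spacing_min	spacing_max	version
LAGLIDADG	LHE	LAGLIDADG	3	2	80	150	1
RT_catalytic	RTM	[YF].DD	0	1	NA	NA	1
RT_block_3	RTM_support	GLSQG	1	1	NA	NA	1
RT_block_7	RTM_support	PRKHS	1	1	NA	NA	1
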