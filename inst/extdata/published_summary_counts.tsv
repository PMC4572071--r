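quantity	numerator	denominator
roh_singletons	15	48
testis_max_expression	41	143
testis_expressed	119	143
novel_hlofs	76	173
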