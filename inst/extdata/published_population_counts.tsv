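population	n_individuals	n_hlofs
GS_SFHS	844	137
CROATIA_Vis	193	104
ORCADES	197	103
NSPHS	98	91
CROATIA_Korcula	100	74
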