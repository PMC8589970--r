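gene	role	efficiency_percent	r_squared	amplicon_length	annealing_temp
ACT	reference	91.4	0.994	151	64
ARF1	reference	94.8	0.998	157	60
CYP28	reference	99.9	0.997	146	62
EF1A	reference	108.2	0.998	157	56
GAPC	reference	106.7	0.999	151	58
RPL23A	reference	88.2	0.999	166	60
RCA	reference	105.6	0.999	167	54
SPS	reference	99.8	0.997	152	62
TBP	reference	90.5	0.999	175	64
UBC	reference	92.6	0.998	149	60
UBQ	reference	98.6	0.998	156	60
ABCC10	validation	113.4	0.998	113	60
CYP89A2	validation	103.0	0.998	170	60
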