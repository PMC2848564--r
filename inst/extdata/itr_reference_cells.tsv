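label	N	P	k	isi_ms	printed_bits_per_minute
C300_P90_k15	5	0.90	15	300	4.41
C300_P94_k11	5	0.94	11	300	6.81
C300_P94_k12	5	0.94	12	300	6.25
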