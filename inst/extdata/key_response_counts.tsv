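unit_type	unit	rt_mean_ms	rt_sd_ms	hits	false_alarms	misses	error_printed_pct
subject	VPja	456	128	72	3	0	4
subject	VPiz	479	148	71	0	1	1.4
subject	VPip	507	174	72	1	0	1.4
subject	VPzq	360	82	71	5	1	7.8
subject	VPig	612	219	88	17	8	22.1
subject	VPjf	360	131	96	4	0	4
subject	VPjb	450	113	95	3	1	4
direction	Front	483	168	67	8	1	11.8
direction	Front-right	414	121	40	1	4	11.1
direction	Right	431	126	84	3	0	3.5
direction	Back-right	552	211	83	10	1	11.7
direction	Back	518	242	57	1	3	6.6
direction	Back-left	499	184	51	4	1	8.9
direction	Left	408	100	108	5	0	4.4
direction	Front-left	403	121	75	1	1	2.6
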