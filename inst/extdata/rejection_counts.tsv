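subject	condition	n_rejected	n_total	printed_pct
VPiz	C1000	1497	2560	58.48
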