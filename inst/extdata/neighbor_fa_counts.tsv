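n_neighbor	n_other	n_targets	n_directions
14	19	576	8
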