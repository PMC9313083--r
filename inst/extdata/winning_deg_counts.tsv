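category	direction	n	printed_total
common	down	140	296
common	up	156	296
unique_lc	down	57	98
unique_lc	up	41	98
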