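analysis	sensitivity	specificity	fpr	auroc	n_pos	n_neg
de	1	1	0	0.95999999999999996	5	25
as	0.40000000000000002	1	0	1	5	25
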