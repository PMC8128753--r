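gene_id	mean_NZO	mean_C3H	log2_ratio	ratio	wilcoxon_p	p_bh	present_NZO	present_C3H	de_flag	direction
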