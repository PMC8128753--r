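gene_id	category
G00010	de_only
G00016	de_only
G00018	de_only
G00024	de_only
G00013	as_only
G00011	both
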