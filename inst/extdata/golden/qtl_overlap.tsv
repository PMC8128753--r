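name	chrom	window_start	window_end	phenotypes	de_genes	as_genes	n_de	n_as
toyQTL1	chr1	1	15000	blood glucose			0	0
toyQTL2	chr2	1	15000	plasma insulin			0	0
toyQTL3	chr12	40000000	60000000	blood glucose			0	0
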