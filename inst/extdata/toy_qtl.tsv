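name	chrom	marker_pos_mb	window_mb	phenotypes
toyQTL1	chr1	0.005	0.01	blood glucose
toyQTL2	chr2	0.005	0.01	plasma insulin
toyQTL3	chr12	50	10	blood glucose
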