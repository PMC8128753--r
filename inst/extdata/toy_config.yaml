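# Packaged toy pipeline configuration: a small simulated two-strain
# experiment exercising every stage, used for end-to-end determinism
# checks and as a worked example.
seed: 7
simulate:
  n_genes: 30
  exon_count_range: [3, 8]
  frac_de: 0.2
  frac_as: 0.2
arh:
  resamples: 1000
qtl:
  path: toy_qtl.tsv
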