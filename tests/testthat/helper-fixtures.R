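# Shared fixture builders.  Everything is generated in code; no stored
# binary data.

# annotation with n_genes x n_exons x probes_per_exon gene probes plus
# background probes spread over GC classes
toy_annotation <- function(n_genes = 2, n_exons = 2, probes_per_exon = 2,
                           n_bg = 4, gc_gene = 10L, gc_bg = 10L) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    for (e in seq_len(n_exons)) {
      for (p in seq_len(probes_per_exon)) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = sprintf("g%d_e%d_p%d", g, e, p),
          gene_id = sprintf("g%d", g), exon_id = sprintf("g%d_e%d", g, e),
          chrom = "chr1", exon_start = g * 10000L + e * 100L,
          exon_end = g * 10000L + e * 100L + 50L,
          gc_count = gc_gene, is_background = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (b in seq_len(n_bg)) {
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = sprintf("bg%d", b), gene_id = "", exon_id = "",
      chrom = "none", exon_start = 0L, exon_end = 0L,
      gc_count = gc_bg, is_background = TRUE, stringsAsFactors = FALSE)
  }
  probe_annotation(do.call(rbind, rows))
}

# matrix over an annotation's probes with the given per-probe values
# (recycled across samples unless a matrix is supplied)
toy_matrix <- function(ann, values, n_per_cond = 2,
                       conditions = c("A", "B")) {
  samples <- c(paste0(conditions[1], seq_len(n_per_cond)),
               paste0(conditions[2], seq_len(n_per_cond)))
  if (is.matrix(values)) v <- values
  else v <- matrix(values, nrow(ann), length(samples))
  dimnames(v) <- list(ann$probe_id, samples)
  probe_matrix(v, setNames(rep(conditions, each = n_per_cond), samples))
}

# expression_summary built directly from a unit x sample matrix
toy_summary <- function(values, conditions, level = "gene",
                        gene_of = NULL) {
  structure(list(values = values, conditions = conditions, level = level,
                 gene_of = gene_of), class = "expression_summary")
}

# random splicing-probability profiles for oracle checks
random_probs <- function(n) {
  w <- rexp(n)
  w / sum(w)
}

# independent KL-divergence-to-uniform oracle (bits)
kl_to_uniform <- function(p) sum(p * log2(p * length(p)))

# run the standard pipeline on a simulation output
run_pipeline <- function(sim, B = 1000, seed = 99) {
  m <- quantile_normalize(gc_baseline_correct(sim$matrix, sim$annotation))
  pres <- presence_call(m, sim$annotation)
  ge <- summarize_probes(m, sim$annotation, "gene")
  ee <- summarize_probes(m, sim$annotation, "exon")
  de <- select_de(ge, pres)
  models <- gene_models(sim$annotation)
  prof <- exon_ratio_profile(ee, models)
  sc <- arh_pvalue(arh_score(prof), prof, B = B, seed = seed)
  list(m = m, presence = pres, de = de, models = models, profile = prof,
       scores = sc)
}
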