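# ARH: entropy-based detection of alternative splicing on exon arrays.
#
# Per gene, each exon's log2 condition ratio is centered on the gene's
# median ratio; the absolute deviations are turned into a "splicing
# probability" distribution p_i = 2^|s_i| / sum_j 2^|s_j|.  A gene whose
# exons all follow the gene-level ratio has uniform p (maximum entropy);
# one or few deviating exons concentrate the mass.  The ARH score is the
# Kullback-Leibler divergence of p from uniform, log2(n) - H(p) bits, so
# a dominating exon yields a high score.

entropy_bits <- function(p) -sum(p * log2(p))

arh_from_dev <- function(s) {
  w <- 2^abs(s)
  p <- w / sum(w)
  log2(length(s)) - entropy_bits(p)
}

#' Per-exon condition log-ratio profiles and splicing probabilities
#'
#' For every gene: `log2_ratio` is the mean (or median) log2 exon
#' expression in the numerator condition minus that in the denominator
#' condition; `deviation` centers each exon's ratio on the gene's median
#' ratio; `splice_prob` is the normalized exponential weight
#' `2^|deviation| / sum(2^|deviation|)`, the distribution whose entropy the
#' ARH score evaluates.  Deviations enter through their absolute value so
#' over- and under-inclusion rank equally.
#'
#' @param exon_expr exon-level [summarize_probes()] result.
#' @param models [gene_models()] table for the same annotation.
#' @param numerator,denominator condition labels orienting the ratio;
#'   default: second and first label in order of appearance.
#' @param center per-condition replicate summary, `"mean"` or `"median"`.
#' @return data.frame of class `exon_ratio_profile`, one row per exon in
#'   genomic order: `gene_id`, `exon_id`, `exon_index`, `chrom`,
#'   `exon_start`, `exon_end`, `mean_<den>`, `mean_<num>`, `log2_ratio`,
#'   `deviation`, `splice_prob`.
#' @export
exon_ratio_profile <- function(exon_expr, models, numerator = NULL,
                               denominator = NULL,
                               center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(exon_expr$level == "exon")
  conds <- unique(unname(exon_expr$conditions))
  denominator <- denominator %||% conds[1]
  numerator <- numerator %||% conds[2]
  key <- paste(models$gene_id, models$exon_id, sep = "\r")
  ekey <- paste(exon_expr$gene_of, rownames(exon_expr$values), sep = "\r")
  mi <- match(key, ekey)
  keep <- !is.na(mi)
  if (!any(keep)) stop("no exon in the models has expression data")
  mod <- models[keep, , drop = FALSE]
  vals <- exon_expr$values[mi[keep], , drop = FALSE]
  cfun <- if (center == "mean") rowMeans else
    function(x) apply(x, 1, stats::median)
  m_num <- cfun(vals[, unname(exon_expr$conditions) == numerator, drop = FALSE])
  m_den <- cfun(vals[, unname(exon_expr$conditions) == denominator, drop = FALSE])
  r <- m_num - m_den
  med <- stats::ave(r, mod$gene_id, FUN = stats::median)
  s <- r - med
  w <- 2^abs(s)
  prob <- w / stats::ave(w, mod$gene_id, FUN = sum)
  out <- data.frame(gene_id = mod$gene_id, exon_id = mod$exon_id,
                    exon_index = mod$exon_index, chrom = mod$chrom,
                    exon_start = mod$exon_start, exon_end = mod$exon_end,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", denominator)]] <- unname(m_den)
  out[[paste0("mean_", numerator)]] <- unname(m_num)
  out$log2_ratio <- unname(r)
  out$deviation <- unname(s)
  out$splice_prob <- unname(prob)
  out <- out[order(out$gene_id, out$exon_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  class(out) <- c("exon_ratio_profile", "data.frame")
  out
}

#' ARH splicing score per gene
#'
#' `ARH = log2(n) - H(p)` bits, where `H` is the Shannon entropy of the
#' gene's splicing probability distribution over its `n` exons -- the
#' Kullback-Leibler divergence of that distribution from uniform.  It is 0
#' when no exon deviates (uniform p) and approaches `log2(n)` as a single
#' exon takes all the mass.  Two-exon genes always score 0 (median
#' centering forces `|s_1| = |s_2|`), so genes with fewer than three exons
#' are exempt from significance testing downstream.
#'
#' @param profile an [exon_ratio_profile()].
#' @return data.frame of class `arh_result`: `gene_id`, `n_exons`,
#'   `entropy`, `arh` (bits).
#' @export
arh_score <- function(profile) {
  if (!nrow(profile)) stop("empty profile: gene with no exons")
  sp <- split(profile$splice_prob, profile$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_exons = lengths(sp),
    entropy = vapply(sp, entropy_bits, numeric(1)),
    arh = vapply(sp, function(p) log2(length(p)) - entropy_bits(p),
                 numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("arh_result", "data.frame")
  out
}

#' Resampling p-values for ARH scores
#'
#' The null model is built per exon-count stratum from the data themselves:
#' the exon deviations of all genes are pooled, and for every stratum of
#' `n` exons, `B` null genes are formed by drawing `n` deviations with
#' replacement from the pool and pushing them through the same pipeline
#' (median re-centering, exponential weighting, entropy).  Each gene's
#' p-value is `(1 + #{null ARH >= observed}) / (B + 1)` within its stratum
#' (add-one correction, so p is never 0).  Genes with fewer than
#' `min_exons` exons are exempt: their forced near-zero score is untestable
#' under this model and they receive `p = 1`.  Deterministic given `seed`.
#'
#' @param scores an [arh_score()] table.
#' @param profile the matching [exon_ratio_profile()] (supplies the
#'   deviation pool).
#' @param B number of resamples per stratum (default 10000).
#' @param seed integer seed (mandatory: resampling must be reproducible).
#' @param min_exons smallest testable exon count (default 3).
#' @param alpha significance cutoff on the resampling p (default 0.05).
#' @return `scores` with columns `p_value` and `significant` added.
#' @export
arh_pvalue <- function(scores, profile, B = 10000, seed, min_exons = 3,
                       alpha = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  if (B < 1) stop("B must be at least 1")
  pool <- profile$deviation
  if (length(unique(profile$gene_id)) < 2)
    stop("deviation pool needs more than one gene")
  set.seed(seed)
  p_value <- rep(1, nrow(scores))
  testable <- scores$n_exons >= min_exons
  for (n in sort(unique(scores$n_exons[testable]))) {
    draws <- matrix(sample(pool, B * n, replace = TRUE), nrow = B)
    draws <- draws - apply(draws, 1, stats::median)
    w <- 2^abs(draws)
    p <- w / rowSums(w)
    null_arh <- log2(n) + rowSums(p * log2(p))
    null_sorted <- sort(null_arh)
    idx <- which(testable & scores$n_exons == n)
    n_ge <- B - findInterval(scores$arh[idx], null_sorted, left.open = TRUE)
    p_value[idx] <- (1 + n_ge) / (B + 1)
  }
  scores$p_value <- p_value
  scores$significant <- testable & p_value <= alpha
  scores
}

#' Flag the exons driving a significant splicing call
#'
#' Within genes whose ARH p-value is significant, an exon is flagged as an
#' alternative-splicing event when its splicing probability is at least
#' `multiplier` times the uniform mass `1/n` -- i.e. it carries at least
#' `multiplier`-fold its fair share of the deviation distribution.
#'
#' @param profile an [exon_ratio_profile()].
#' @param results an [arh_pvalue()] table with `significant` column.
#' @param multiplier fold-above-uniform cutoff `c` in `p_i >= c/n`
#'   (default 2).
#' @return `profile` with a logical `flagged` column (always `FALSE` in
#'   non-significant genes).
#' @export
flag_exons <- function(profile, results, multiplier = 2) {
  ri <- match(profile$gene_id, results$gene_id)
  if (anyNA(ri)) stop("profile gene(s) missing from ARH results")
  n <- results$n_exons[ri]
  profile$flagged <- results$significant[ri] &
    profile$splice_prob >= multiplier / n
  profile
}

#' Exon-level alternative-splicing table
#'
#' One row per exon of every scored gene, combining the per-exon profile
#' with the gene-level ARH statistics -- the layout used to report all
#' significant splicing events with their exact exon positions.
#'
#' @param profile a [flag_exons()]-annotated (or plain) profile.
#' @param results an [arh_pvalue()] table.
#' @return data.frame with per-exon ratios, deviations, splicing
#'   probabilities, the gene ARH score/p, and the exon significance flag.
#' @export
as_exon_table <- function(profile, results) {
  if (is.null(profile$flagged)) profile <- flag_exons(profile, results)
  ri <- match(profile$gene_id, results$gene_id)
  out <- as.data.frame(profile)
  out$n_exons <- results$n_exons[ri]
  out$gene_arh <- results$arh[ri]
  out$gene_p <- results$p_value[ri]
  out$gene_significant <- results$significant[ri]
  out
}

#' Plot-ready exon expression profile for one gene
#'
#' One row per exon in genomic order, with the mean log2 expression in
#' each condition and the exon's splicing probability -- sufficient to
#' redraw the classic exon-profile panel (expression lines per condition,
#' probability bars).
#'
#' @param gene_id gene to extract.
#' @param profile an [exon_ratio_profile()].
#' @return data.frame with `exon_id`, `exon_index`, `exon_start`,
#'   `exon_end`, the two condition means, and `splice_prob`.
#' @export
exon_profile_table <- function(gene_id, profile) {
  rows <- profile$gene_id == gene_id
  if (!any(rows)) stop("unknown gene: ", gene_id)
  num <- attr(profile, "numerator"); den <- attr(profile, "denominator")
  cols <- c("exon_id", "exon_index", "exon_start", "exon_end",
            paste0("mean_", den), paste0("mean_", num), "splice_prob")
  out <- as.data.frame(profile)[rows, cols, drop = FALSE]
  out <- out[order(out$exon_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition flagged genes into DE-only, AS-only and both
#'
#' @param de a [select_de()] table.
#' @param as_res an [arh_pvalue()] table.
#' @return list with character vectors `de_only`, `as_only`, `both` --
#'   a disjoint partition of all flagged genes.
#' @export
overlap_de_as <- function(de, as_res) {
  de_genes <- de$gene_id[de$de_flag]
  as_genes <- as_res$gene_id[as_res$significant]
  list(de_only = sort(setdiff(de_genes, as_genes)),
       as_only = sort(setdiff(as_genes, de_genes)),
       both = sort(intersect(de_genes, as_genes)))
}
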