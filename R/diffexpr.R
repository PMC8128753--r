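.comb_env <- new.env(parent = emptyenv())

# All C(N, n) assignments of the pooled observations to the first group,
# as an n x C(N, n) index matrix.  Cached for the small replicate-group
# sizes the exact test is meant for.
comb_indices <- function(N, n) {
  key <- paste(N, n, sep = "_")
  hit <- .comb_env[[key]]
  if (!is.null(hit)) return(hit)
  if (choose(N, n) > 3e6)
    stop("group sizes too large for exact enumeration (choose(N, n) > 3e6)")
  cmb <- utils::combn(N, n)
  if (choose(N, n) <= 2e5) .comb_env[[key]] <- cmb
  cmb
}

#' Exact two-sided Wilcoxon rank-sum test by full enumeration
#'
#' The permutation-exact two-sided rank-sum test for small replicate
#' groups: all `choose(|a|+|b|, |a|)` assignments of the pooled midranks to
#' the first group are enumerated, and the p-value is the fraction of
#' assignments whose rank sum deviates from its null expectation
#' `n (N + 1) / 2` by at least the observed deviation.  Ties are handled by
#' midranks inside the enumeration, so the test remains exact with tied
#' values (unlike the classical null distribution, which assumes none).
#'
#' @param a,b numeric vectors of replicate values (each nonempty; the
#'   enumeration regime is roughly 2-12 per group).
#' @return exact two-sided p-value in (0, 1].
#' @examples
#' wilcoxon_exact(1:5, 6:10)   # 2/252, the smallest 5-vs-5 p
#' @export
wilcoxon_exact <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty replicate group")
  n <- length(a); N <- n + length(b)
  r <- rank(c(a, b))
  cmb <- comb_indices(N, n)
  sums <- colSums(matrix(r[cmb], nrow = n))
  expected <- n * (N + 1) / 2
  obs_dev <- abs(sum(r[seq_len(n)]) - expected)
  mean(abs(sums - expected) >= obs_dev)
}

#' Gene-level differential-expression selection
#'
#' A gene is flagged differentially expressed when all three criteria hold:
#' (1) it is called present in at least one condition; (2) its
#' between-condition expression ratio is at least `ratio_high` or at most
#' `ratio_low` (both inclusive); (3) the exact two-sided Wilcoxon test
#' between the per-replicate gene expression values has p <= `alpha`
#' (inclusive).  The ratio is `2^(m_num - m_den)` where `m_num`/`m_den` are
#' the condition summaries (mean of per-replicate log2 values by default,
#' medians via `center = "median"`) of the numerator and denominator
#' conditions.  A Benjamini-Hochberg adjusted p-value column is emitted for
#' reference but never gates the DE flag.
#'
#' @param expr gene-level [summarize_probes()] result.
#' @param presence [presence_call()] result covering the same genes.
#' @param numerator,denominator condition labels orienting the ratio
#'   (log2_ratio = log2\[numerator/denominator\]); default: second and first
#'   label in order of appearance in the sample map.
#' @param ratio_low,ratio_high fold-change cutoffs (defaults 0.75 and 1.33).
#' @param alpha Wilcoxon significance cutoff (default 0.05).
#' @param center per-condition replicate summary, `"mean"` or `"median"`.
#' @return data.frame of class `de_result`: `gene_id`, `mean_<den>`,
#'   `mean_<num>`, `log2_ratio`, `ratio`, `wilcoxon_p`, `p_bh`,
#'   `present_<den>`, `present_<num>`, `de_flag`, `direction`.
#' @export
select_de <- function(expr, presence, numerator = NULL, denominator = NULL,
                      ratio_low = 0.75, ratio_high = 1.33, alpha = 0.05,
                      center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(expr$level == "gene")
  conds <- unique(unname(expr$conditions))
  denominator <- denominator %||% conds[1]
  numerator <- numerator %||% conds[2]
  if (!all(c(numerator, denominator) %in% conds))
    stop("numerator/denominator must be the two condition labels")
  genes <- rownames(expr$values)
  pidx <- match(genes, presence$gene_id)
  if (anyNA(pidx))
    stop("gene(s) missing from presence table: ",
         paste(genes[is.na(pidx)], collapse = ", "))
  cols_num <- which(unname(expr$conditions) == numerator)
  cols_den <- which(unname(expr$conditions) == denominator)
  cfun <- if (center == "mean") rowMeans else
    function(x) apply(x, 1, stats::median)
  m_num <- cfun(expr$values[, cols_num, drop = FALSE])
  m_den <- cfun(expr$values[, cols_den, drop = FALSE])
  log2_ratio <- m_num - m_den
  p <- vapply(seq_along(genes), function(i)
    wilcoxon_exact(expr$values[i, cols_den], expr$values[i, cols_num]),
    numeric(1))
  pres_num <- presence[[paste0("present_", numerator)]][pidx]
  pres_den <- presence[[paste0("present_", denominator)]][pidx]
  ratio <- 2^log2_ratio
  de_flag <- (pres_num | pres_den) &
    (ratio >= ratio_high | ratio <= ratio_low) & p <= alpha
  direction <- ifelse(!de_flag, "none",
                      ifelse(log2_ratio > 0, paste0("up_in_", numerator),
                             paste0("up_in_", denominator)))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out[[paste0("mean_", denominator)]] <- unname(m_den)
  out[[paste0("mean_", numerator)]] <- unname(m_num)
  out$log2_ratio <- unname(log2_ratio)
  out$ratio <- unname(ratio)
  out$wilcoxon_p <- p
  out$p_bh <- stats::p.adjust(p, method = "BH")
  out[[paste0("present_", denominator)]] <- pres_den
  out[[paste0("present_", numerator)]] <- pres_num
  out$de_flag <- unname(de_flag)
  out$direction <- direction
  rownames(out) <- NULL
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  class(out) <- c("de_result", "data.frame")
  out
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per group, dCt is the mean target Ct minus the mean reference-gene Ct
#' (the endogenous control, e.g. Tbp); ddCt is the sample group's dCt minus
#' the calibrator group's; the returned fold change is `2^-ddCt`.
#'
#' @param sample,calibrator data.frames with numeric columns `ct_target`
#'   and `ct_reference` (one row per replicate), nonempty, finite, > 0.
#' @return linear-scale fold change of the sample group relative to the
#'   calibrator.
#' @export
ddct_fold_change <- function(sample, calibrator) {
  check <- function(df, what) {
    if (!nrow(df)) stop(what, " group is empty")
    for (col in c("ct_target", "ct_reference")) {
      if (is.null(df[[col]])) stop(what, " group missing column ", col)
      if (anyNA(df[[col]]) || any(!is.finite(df[[col]])) || any(df[[col]] <= 0))
        stop(what, " group has missing or non-positive Ct in ", col)
    }
  }
  check(sample, "sample"); check(calibrator, "calibrator")
  dct_s <- mean(sample$ct_target) - mean(sample$ct_reference)
  dct_c <- mean(calibrator$ct_target) - mean(calibrator$ct_reference)
  2^(-(dct_s - dct_c))
}
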