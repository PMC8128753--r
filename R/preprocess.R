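#' GC-stratified background baseline correction
#'
#' Within-array baseline correction against the background control probes.
#' For each array, every probe's log2 value is reduced by the median log2
#' value of the background probes in the same GC class (same integer G+C
#' count).  GC classes holding fewer than `min_bin` background probes fall
#' back to that array's global background median.  Background probes are
#' corrected the same way, so downstream presence thresholds remain
#' GC-matched.
#'
#' @param m a [probe_matrix()].
#' @param ann a [probe_annotation()] covering the matrix's probes.
#' @param min_bin minimum background probes a GC class needs before its own
#'   median is used (default 30).
#' @return corrected `probe_matrix`.
#' @export
gc_baseline_correct <- function(m, ann, min_bin = 30) {
  ann <- ann[match(rownames(m$values), ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("probe(s) in matrix absent from annotation")
  bg <- which(ann$is_background)
  if (!length(bg)) stop("no background probes in annotation")
  gc <- ann$gc_count
  bins <- sort(unique(gc))
  bg_by_bin <- split(bg, gc[bg])
  counts <- lengths(bg_by_bin)
  vals <- m$values
  out <- vals
  for (j in seq_len(ncol(vals))) {
    global_med <- stats::median(vals[bg, j])
    med_of <- vapply(as.character(bins), function(b) {
      idx <- bg_by_bin[[b]]
      if (is.null(idx) || length(idx) < min_bin) global_med
      else stats::median(vals[idx, j])
    }, numeric(1))
    out[, j] <- vals[, j] - med_of[as.character(gc)]
  }
  probe_matrix(out, m$conditions)
}

#' Quantile normalization across arrays
#'
#' Forces every array to share one common value distribution: each column's
#' values are replaced by the mean, across columns, of the values at the
#' same rank; ties within a column receive the mean of the reference values
#' at their tied ranks.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param m a [probe_matrix()].
#' @return normalized `probe_matrix`.  A single-sample matrix is returned
#'   unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m$values) < 2L) {
    warning("single-sample matrix: quantile normalization skipped")
    return(m)
  }
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  probe_matrix(v, m$conditions)
}

#' Summarize probes to exon or gene level
#'
#' Per unit and sample, the median of the unit's probe values: at exon
#' level the probes annotated to the exon, at gene level all probes of all
#' the gene's exons.  Units with zero probes in the matrix are excluded
#' with a message.
#'
#' @param m a normalized [probe_matrix()].
#' @param ann a [probe_annotation()].
#' @param level `"gene"` or `"exon"`.
#' @return object of class `expression_summary`: list with `values`
#'   (unit x sample matrix), `conditions`, `level`, and for exon level a
#'   `gene_of` vector mapping exon id to gene id.
#' @export
summarize_probes <- function(m, ann, level = c("gene", "exon")) {
  level <- match.arg(level)
  g <- ann[!ann$is_background & ann$probe_id %in% rownames(m$values), ,
           drop = FALSE]
  unit <- if (level == "gene") g$gene_id else paste(g$gene_id, g$exon_id,
                                                   sep = "\r")
  all_units <- if (level == "gene") unique(ann$gene_id[!ann$is_background])
               else unique(paste(ann$gene_id, ann$exon_id,
                                 sep = "\r")[!ann$is_background])
  dropped <- setdiff(all_units, unique(unit))
  if (length(dropped))
    message(length(dropped), " unit(s) with zero probes excluded at ",
            level, " level")
  idx <- split(match(g$probe_id, rownames(m$values)), unit)
  vals <- t(vapply(idx, function(i)
    apply(m$values[i, , drop = FALSE], 2, stats::median),
    numeric(ncol(m$values))))
  colnames(vals) <- colnames(m$values)
  if (level == "exon") {
    parts <- strsplit(rownames(vals), "\r", fixed = TRUE)
    gene_of <- vapply(parts, `[[`, "", 1L)
    rownames(vals) <- vapply(parts, `[[`, "", 2L)
    names(gene_of) <- rownames(vals)
  } else gene_of <- NULL
  structure(list(values = vals, conditions = m$conditions, level = level,
                 gene_of = gene_of),
            class = "expression_summary")
}

#' @export
print.expression_summary <- function(x, ...) {
  cat(sprintf("expression_summary (%s level): %d units x %d samples\n",
              x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Present/absent calls against GC-matched background
#'
#' Per condition, the detection threshold for each GC class is the 75th
#' percentile (linear interpolation between order statistics,
#' `h = (n-1) q`) of that class's background probe values pooled over the
#' condition's arrays; classes with fewer than `min_bin` background probes
#' fall back to the pooled global background percentile.  A probe-sample
#' value counts as above background when it is strictly greater than its
#' probe's threshold, and a gene is called present in a condition when
#' strictly more than `fraction` of its exon probe values (pooled over the
#' condition's arrays) are above.
#'
#' @param m GC-corrected, quantile-normalized [probe_matrix()].
#' @param ann a [probe_annotation()].
#' @param q background percentile (default 0.75).
#' @param fraction presence fraction cutoff (default 0.5; strict `>`).
#' @param min_bin minimum background probes per GC class (default 30).
#' @return data.frame of class `presence_call`: `gene_id`, then per
#'   condition `frac_<cond>` and `present_<cond>`, plus `present_any`.
#' @export
presence_call <- function(m, ann, q = 0.75, fraction = 0.5, min_bin = 30) {
  ann <- ann[match(rownames(m$values), ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("probe(s) in matrix absent from annotation")
  bg <- which(ann$is_background)
  if (!length(bg)) stop("no background probes in annotation")
  conds <- unique(unname(m$conditions))
  gene_rows <- which(!ann$is_background)
  genes <- sort(unique(ann$gene_id[gene_rows]))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  bg_by_bin <- split(bg, ann$gc_count[bg])
  for (cond in conds) {
    cols <- which(unname(m$conditions) == cond)
    pool <- as.vector(m$values[bg, cols])
    global_thr <- stats::quantile(pool, q, type = 7, names = FALSE)
    thr_of <- vapply(names(bg_by_bin), function(b) {
      idx <- bg_by_bin[[b]]
      if (length(idx) < min_bin) global_thr
      else stats::quantile(as.vector(m$values[idx, cols]), q, type = 7,
                           names = FALSE)
    }, numeric(1))
    probe_thr <- thr_of[as.character(ann$gc_count[gene_rows])]
    probe_thr[is.na(probe_thr)] <- global_thr
    above <- m$values[gene_rows, cols, drop = FALSE] > probe_thr
    frac <- vapply(split(seq_along(gene_rows), ann$gene_id[gene_rows]),
                   function(i) mean(above[i, , drop = FALSE]), numeric(1))
    out[[paste0("frac_", cond)]] <- unname(frac[genes])
    out[[paste0("present_", cond)]] <- unname(frac[genes]) > fraction
  }
  out$present_any <- Reduce(`|`, out[paste0("present_", conds)])
  class(out) <- c("presence_call", "data.frame")
  out
}
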