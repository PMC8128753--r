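#' Parameters for the probe-level two-condition simulator
#'
#' Defaults emulate the structure of a two-strain exon-array islet
#' experiment: two conditions with 5 replicate arrays each, genes of 3-16
#' exons carrying 1-4 probes per exon, GC classes spanning 8-17 G/C bases,
#' and 30 background control probes per GC class (so every class clears
#' the GC-correction minimum).  All log2-scale magnitudes: gene baselines
#' N(7, 1.5^2), probe affinities N(0, 0.3^2), replicate noise N(0, 0.25^2),
#' a linear GC trend of 0.05 per G/C base, background signal N(3, 0.5^2).
#' Spiked differential expression defaults to a log2 fold change of
#' magnitude 1 with random sign; spiked alternative splicing is
#' cassette-exon style -- `as_n_exons` exon(s) of the gene shifted by
#' `as_shift` log2 units (random sign) in the numerator condition only.
#'
#' @param n_genes number of genes (default 1000).
#' @param exon_count_range inclusive integer range of exons per gene
#'   (uniform; default `c(3, 16)`).
#' @param probes_per_exon inclusive integer range of probes per exon
#'   (uniform; default `c(1, 4)`).
#' @param n_replicates arrays per condition (default 5).
#' @param conditions two condition labels, denominator first
#'   (default `c("NZO", "C3H")`).
#' @param baseline_mean,baseline_sd gene baseline log2 expression.
#' @param affinity_sd per-probe affinity spread (constant across arrays).
#' @param gc_slope log2 units per G/C base, applied around the mean GC.
#' @param noise_sd replicate measurement noise.
#' @param frac_absent fraction of genes expressed at background level.
#' @param frac_de fraction of (non-absent) genes spiked as DE.
#' @param de_lfc magnitude of the spiked log2 fold change (sign random).
#' @param frac_as fraction of eligible genes spiked with a splicing event.
#' @param as_shift cassette-exon log2 shift magnitude (sign random).
#' @param as_n_exons exons affected per splicing event (default 1).
#' @param gc_range inclusive GC-count range of probes (default `c(8, 17)`).
#' @param bg_probes_per_bin background probes per GC class (default 30).
#' @param bg_mean,bg_sd background signal level and spread.
#' @param seed integer seed; mandatory.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 1000, exon_count_range = c(3L, 16L),
                       probes_per_exon = c(1L, 4L), n_replicates = 5,
                       conditions = c("NZO", "C3H"),
                       baseline_mean = 7, baseline_sd = 1.5,
                       affinity_sd = 0.3, gc_slope = 0.05, noise_sd = 0.25,
                       frac_absent = 0.1, frac_de = 0.1, de_lfc = 1,
                       frac_as = 0.05, as_shift = 2, as_n_exons = 1,
                       gc_range = c(8L, 17L), bg_probes_per_bin = 30,
                       bg_mean = 3, bg_sd = 0.5, seed) {
  if (missing(seed)) seed <- NULL
  p <- list(n_genes = n_genes, exon_count_range = as.integer(exon_count_range),
            probes_per_exon = as.integer(probes_per_exon),
            n_replicates = n_replicates, conditions = conditions,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            affinity_sd = affinity_sd, gc_slope = gc_slope,
            noise_sd = noise_sd, frac_absent = frac_absent,
            frac_de = frac_de, de_lfc = de_lfc, frac_as = frac_as,
            as_shift = as_shift, as_n_exons = as_n_exons,
            gc_range = as.integer(gc_range),
            bg_probes_per_bin = bg_probes_per_bin,
            bg_mean = bg_mean, bg_sd = bg_sd, seed = seed)
  bad <- character()
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(is.numeric(p$n_genes) && p$n_genes >= 1, "n_genes")
  chk(length(p$exon_count_range) == 2 && p$exon_count_range[1] >= 1 &&
        p$exon_count_range[1] <= p$exon_count_range[2], "exon_count_range")
  chk(length(p$probes_per_exon) == 2 && p$probes_per_exon[1] >= 1 &&
        p$probes_per_exon[1] <= p$probes_per_exon[2], "probes_per_exon")
  chk(is.numeric(p$n_replicates) && p$n_replicates >= 2, "n_replicates")
  chk(length(p$conditions) == 2 && !anyDuplicated(p$conditions), "conditions")
  for (f in c("baseline_sd", "affinity_sd", "noise_sd", "bg_sd"))
    chk(is.numeric(p[[f]]) && p[[f]] >= 0, f)
  for (f in c("frac_absent", "frac_de", "frac_as"))
    chk(is.numeric(p[[f]]) && p[[f]] >= 0 && p[[f]] <= 1, f)
  chk(length(p$gc_range) == 2 && p$gc_range[1] >= 0 &&
        p$gc_range[1] <= p$gc_range[2], "gc_range")
  chk(is.numeric(p$bg_probes_per_bin) && p$bg_probes_per_bin >= 1,
      "bg_probes_per_bin")
  chk(is.numeric(p$as_n_exons) && p$as_n_exons >= 1, "as_n_exons")
  chk(is.numeric(p$seed %||% NA) && length(p$seed %||% NA) == 1 &&
        !is.na(p$seed %||% NA), "seed")
  if (length(bad))
    stop("invalid simulation parameter(s): ", paste(bad, collapse = ", "))
  class(p) <- "sim_params"
  p
}

#' Simulate a probe-level two-condition exon-array experiment
#'
#' Each probe's log2 value is the sum of its gene's baseline, the
#' condition effect for spiked DE genes, the cassette-exon shift for
#' spiked splicing events (affected exons, numerator condition only), a
#' per-probe affinity, a linear GC trend, and replicate noise.  Absent
#' genes are drawn at background level instead of a baseline.  Background
#' control probes are drawn per GC class from the background distribution
#' with the same GC trend, so GC correction and GC-matched presence
#' thresholds behave as they would on a real array.  The same parameters
#' and seed always reproduce the identical dataset.
#'
#' @param params a [sim_params()] object.
#' @return list with `matrix` (a [probe_matrix()]), `annotation`
#'   (a [probe_annotation()]) and `truth` (data.frame: `gene_id`,
#'   `absent_flag`, `de_flag`, `true_lfc` on the numerator/denominator
#'   scale, `as_flag`, `as_exons` comma-joined, `as_shift`, `n_exons`).
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  nrep <- p$n_replicates
  cond_a <- p$conditions[1]; cond_b <- p$conditions[2]
  samples <- c(paste0(cond_a, "_", seq_len(nrep)),
               paste0(cond_b, "_", seq_len(nrep)))
  cond_of <- stats::setNames(rep(p$conditions, each = nrep), samples)
  is_b <- unname(cond_of) == cond_b

  ng <- as.integer(p$n_genes)
  gene_ids <- sprintf("G%05d", seq_len(ng))
  n_exons <- sample(seq(p$exon_count_range[1], p$exon_count_range[2]),
                    ng, replace = TRUE)
  absent <- stats::runif(ng) < p$frac_absent
  de <- !absent & stats::runif(ng) < p$frac_de
  lfc <- ifelse(de, p$de_lfc * sample(c(-1, 1), ng, replace = TRUE), 0)
  as_eligible <- !absent & n_exons >= p$as_n_exons + 1
  as_flag <- as_eligible & stats::runif(ng) < p$frac_as
  as_sign <- sample(c(-1, 1), ng, replace = TRUE)
  baseline <- ifelse(absent,
                     stats::rnorm(ng, p$bg_mean, p$bg_sd),
                     stats::rnorm(ng, p$baseline_mean, p$baseline_sd))

  gc_lo <- p$gc_range[1]; gc_hi <- p$gc_range[2]
  gc_mean <- (gc_lo + gc_hi) / 2
  chroms <- paste0("chr", 1 + (seq_len(ng) - 1L) %% 19L)

  ann_list <- vector("list", ng)
  val_list <- vector("list", ng)
  as_exons_of <- character(ng)
  pos <- integer(19); names(pos) <- paste0("chr", 1:19)
  for (g in seq_len(ng)) {
    ne <- n_exons[g]
    exon_ids <- sprintf("%s_E%02d", gene_ids[g], seq_len(ne))
    npe <- sample(seq(p$probes_per_exon[1], p$probes_per_exon[2]),
                  ne, replace = TRUE)
    ch <- chroms[g]
    starts <- pos[ch] + 1000L + (seq_len(ne) - 1L) * 500L
    ends <- starts + 199L
    pos[ch] <- ends[ne]
    aff_exon <- rep(seq_len(ne), npe)
    np <- sum(npe)
    probe_ids <- sprintf("%s_P%d", exon_ids[aff_exon],
                         unlist(lapply(npe, seq_len)))
    gc <- sample(gc_lo:gc_hi, np, replace = TRUE)
    affected <- if (as_flag[g])
      sample(seq_len(ne), p$as_n_exons) else integer()
    as_exons_of[g] <- paste(exon_ids[affected], collapse = ",")
    mu <- baseline[g] + p$affinity_sd * stats::rnorm(np) +
      p$gc_slope * (gc - gc_mean)
    shift_b <- lfc[g] +
      ifelse(aff_exon %in% affected, as_sign[g] * p$as_shift, 0)
    m <- matrix(mu, np, 2 * nrep) +
      outer(shift_b, as.numeric(is_b)) +
      matrix(stats::rnorm(np * 2 * nrep, 0, p$noise_sd), np)
    val_list[[g]] <- m
    ann_list[[g]] <- data.frame(
      probe_id = probe_ids, gene_id = gene_ids[g],
      exon_id = exon_ids[aff_exon], chrom = ch,
      exon_start = starts[aff_exon], exon_end = ends[aff_exon],
      gc_count = gc, is_background = FALSE, stringsAsFactors = FALSE)
  }

  nbin <- p$bg_probes_per_bin
  bg_gc <- rep(gc_lo:gc_hi, each = nbin)
  nbg <- length(bg_gc)
  bg_ids <- sprintf("BG_gc%02d_%03d", bg_gc, rep(seq_len(nbin),
                                                 gc_hi - gc_lo + 1))
  bg_vals <- matrix(p$bg_mean + p$gc_slope * (bg_gc - gc_mean), nbg,
                    2 * nrep) +
    matrix(stats::rnorm(nbg * 2 * nrep, 0, p$bg_sd), nbg)
  bg_ann <- data.frame(probe_id = bg_ids, gene_id = "", exon_id = "",
                       chrom = "none", exon_start = 0L, exon_end = 0L,
                       gc_count = bg_gc, is_background = TRUE,
                       stringsAsFactors = FALSE)

  ann <- probe_annotation(rbind(do.call(rbind, ann_list), bg_ann))
  vals <- rbind(do.call(rbind, val_list), bg_vals)
  dimnames(vals) <- list(ann$probe_id, samples)
  truth <- data.frame(gene_id = gene_ids, absent_flag = absent,
                      de_flag = de, true_lfc = lfc, as_flag = as_flag,
                      as_exons = as_exons_of,
                      as_shift = ifelse(as_flag, as_sign * p$as_shift, 0),
                      n_exons = n_exons, stringsAsFactors = FALSE)
  list(matrix = probe_matrix(vals, cond_of), annotation = ann,
       truth = truth)
}

auroc_or_na <- function(truth_flag, score) {
  if (length(unique(truth_flag)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = truth_flag, predictor = score,
                                 direction = "<", quiet = TRUE,
                                 levels = c(FALSE, TRUE))))
}

#' Evaluate calls against simulation ground truth
#'
#' Sensitivity, specificity and false-positive rate of the DE and AS
#' flags, plus rank-based AUROC of the underlying scores (DE ranked by
#' descending Wilcoxon significance, AS by the ARH score).  Degenerate
#' cells (e.g. sensitivity with zero true positives in the truth) are
#' reported as `NA`.
#'
#' @param truth the `truth` table from [simulate_experiment()] (or a
#'   subset of its rows).
#' @param de a [select_de()] table on the same gene universe.
#' @param as_res an [arh_pvalue()] table; genes absent from it (e.g. too
#'   few exons) are treated as not called.
#' @return data.frame with one row per analysis (`de`, `as`) and columns
#'   `sensitivity`, `specificity`, `fpr`, `auroc`, `n_pos`, `n_neg`.
#' @export
truth_eval <- function(truth, de, as_res) {
  if (!setequal(truth$gene_id, de$gene_id))
    stop("truth and DE tables cover different gene universes")
  di <- match(truth$gene_id, de$gene_id)
  de_call <- de$de_flag[di]
  de_score <- -log10(de$wilcoxon_p[di])
  ai <- match(truth$gene_id, as_res$gene_id)
  as_call <- ifelse(is.na(ai), FALSE, as_res$significant[ai])
  as_score <- ifelse(is.na(ai), 0, as_res$arh[ai])
  row_for <- function(pos, call, score) {
    tp <- sum(pos & call); fp <- sum(!pos & call)
    fn <- sum(pos & !call); tn <- sum(!pos & !call)
    data.frame(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      fpr = if (tn + fp > 0) fp / (fp + tn) else NA_real_,
      auroc = auroc_or_na(pos, score),
      n_pos = tp + fn, n_neg = fp + tn)
  }
  out <- rbind(row_for(truth$de_flag, de_call, de_score),
               row_for(truth$as_flag, as_call, as_score))
  cbind(data.frame(analysis = c("de", "as"), stringsAsFactors = FALSE), out)
}
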