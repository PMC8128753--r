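#' Gene spans from a gene-model table
#'
#' Collapses the exon table to one locus per gene (chromosome, min exon
#' start, max exon end) -- the coordinates used for QTL localization when
#' no external gene-coordinate table is supplied.
#'
#' @param models a [gene_models()] table.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_loci_from_models <- function(models) {
  sp <- split(models, models$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    chrom = vapply(sp, function(d) d$chrom[1], ""),
    start = vapply(sp, function(d) min(d$exon_start), integer(1)),
    end = vapply(sp, function(d) max(d$exon_end), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Localize DE and AS genes in QTL intervals
#'
#' For each QTL, lists the differentially expressed and alternatively
#' spliced genes whose span intersects the symmetric window
#' `[marker_pos - window, marker_pos + window]` on the same chromosome.
#' Intersection is inclusive at the endpoints (a gene touching the window
#' boundary by a single base is listed).  Loci and QTLs must be on the
#' same genome build; that is the caller's responsibility.
#'
#' @param loci gene coordinates (`gene_id`, `chrom`, `start`, `end`), e.g.
#'   from [read_gene_loci()] or [gene_loci_from_models()].
#' @param qtls QTL table (`name`, `chrom`, `marker_pos`, `window`,
#'   optional `phenotypes`), e.g. from [read_qtl_intervals()].
#' @param de a [select_de()] table.
#' @param as_res an [arh_pvalue()] table.
#' @return data.frame, one row per QTL: window bounds, comma-joined
#'   `de_genes` / `as_genes` and their counts.  A QTL on a chromosome with
#'   no loci yields a warning and an empty row.
#' @export
qtl_overlap <- function(loci, qtls, de, as_res) {
  de_set <- de$gene_id[de$de_flag]
  as_set <- as_res$gene_id[as_res$significant]
  chrom_levels <- union(loci$chrom, qtls$chrom)
  gr_loci <- GenomicRanges::GRanges(
    factor(loci$chrom, levels = chrom_levels),
    IRanges::IRanges(loci$start, loci$end))
  win_start <- pmax(1, qtls$marker_pos - qtls$window)
  win_end <- qtls$marker_pos + qtls$window
  out <- data.frame(name = qtls$name, chrom = qtls$chrom,
                    window_start = win_start, window_end = win_end,
                    phenotypes = qtls$phenotypes %||% "",
                    stringsAsFactors = FALSE)
  missing_chr <- setdiff(unique(qtls$chrom), unique(loci$chrom))
  if (length(missing_chr))
    warning("QTL chromosome(s) absent from gene loci: ",
            paste(missing_chr, collapse = ", "))
  gr_win <- GenomicRanges::GRanges(
    factor(qtls$chrom, levels = chrom_levels),
    IRanges::IRanges(win_start, win_end))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_loci)
  genes_of <- split(loci$gene_id[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_len(nrow(qtls))))
  out$de_genes <- vapply(genes_of, function(g)
    paste(sort(intersect(g, de_set)), collapse = ","), "")
  out$as_genes <- vapply(genes_of, function(g)
    paste(sort(intersect(g, as_set)), collapse = ","), "")
  out$n_de <- vapply(genes_of, function(g)
    length(intersect(g, de_set)), integer(1))
  out$n_as <- vapply(genes_of, function(g)
    length(intersect(g, as_set)), integer(1))
  rownames(out) <- NULL
  out
}

#' Ranked top tables of extreme DE genes
#'
#' Splits a DE table at two log2-ratio cutoffs: genes strictly below `low`
#' and genes strictly above `high`, each sorted by absolute log2 ratio
#' descending (strongest change first).
#'
#' @param de a [select_de()] table.
#' @param low,high log2-ratio cutoffs (defaults -1.5 and 1.2; strict
#'   inequalities).
#' @param de_only restrict to genes with `de_flag` (default `TRUE`).
#' @return list of two data.frames, `low` and `high`.
#' @export
top_table <- function(de, low = -1.5, high = 1.2, de_only = TRUE) {
  d <- if (de_only) de[de$de_flag, , drop = FALSE] else de
  pick <- function(rows) {
    t <- d[rows, , drop = FALSE]
    t <- t[order(-abs(t$log2_ratio), t$gene_id), , drop = FALSE]
    rownames(t) <- NULL
    t
  }
  list(low = pick(d$log2_ratio < low), high = pick(d$log2_ratio > high))
}

read_config <- function(config) {
  if (is.character(config)) {
    dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    attr(config, "dir") <- dir
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

# relative input paths in a YAML config resolve against the config file's
# directory
resolve_path <- function(p, config) {
  base <- attr(config, "dir")
  if (is.null(p) || is.null(base)) return(p)
  if (grepl("^(/|~)", p) || file.exists(p)) p else file.path(base, p)
}

#' Run the full pipeline end to end
#'
#' Simulate (or ingest) probe data, GC-correct, quantile-normalize, call
#' presence, select DE genes, score and test alternative splicing, and
#' write all result tables plus a run manifest to `outdir`.  Reruns with
#' the same config produce byte-identical outputs.
#'
#' Config fields: `seed` (mandatory, checked before any computation);
#' either `simulate:` (arguments to [sim_params()]) or `inputs:` with
#' `matrix`, `annotation`, `conditions` (sample TSV with columns `sample`,
#' `condition`) and optional `log2_input`; optional `normalize:`
#' (`min_bin`, `presence_q`, `presence_fraction`), `de:` (`numerator`,
#' `denominator`, `ratio_low`, `ratio_high`, `alpha`, `center`), `arh:`
#' (`resamples`, `min_exons`, `alpha`, `exon_flag_multiplier`), `qtl:`
#' (`path`, optional `bed`, optional `genome`), `top:` (`low`, `high`).
#'
#' @param config list or YAML file path.
#' @param outdir output directory (overrides `config$outdir`).
#' @return invisible list with all in-memory results.
#' @export
run_all <- function(config, outdir = NULL) {
  config <- read_config(config)
  if (is.null(config$seed)) stop("config must provide a seed")
  seed <- as.integer(config$seed)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      sim <- simulate_experiment(do.call(sim_params, args))
    })
    m <- sim$matrix; ann <- sim$annotation; truth <- sim$truth
  } else if (!is.null(config$inputs)) {
    ingest <- stage("ingest", {
      cm_df <- read_tsv(resolve_path(config$inputs$conditions, config))
      cm <- stats::setNames(as.character(cm_df$condition),
                            as.character(cm_df$sample))
      ann <- read_probe_annotation(resolve_path(config$inputs$annotation, config),
                                   bed = isTRUE(config$inputs$bed))
      m <- read_probe_matrix(resolve_path(config$inputs$matrix, config), cm,
                             log2_input = isTRUE(config$inputs$log2_input))
      list(m = m, ann = ann)
    })
    m <- ingest$m; ann <- ingest$ann
  } else stop("config needs either a 'simulate' or an 'inputs' block")

  nz <- config$normalize %||% list()
  m <- stage("normalize", quantile_normalize(
    gc_baseline_correct(m, ann, min_bin = nz$min_bin %||% 30)))
  presence <- stage("presence", presence_call(
    m, ann, q = nz$presence_q %||% 0.75,
    fraction = nz$presence_fraction %||% 0.5,
    min_bin = nz$min_bin %||% 30))

  models <- gene_models(ann)
  dcfg <- config$de %||% list()
  gene_expr <- stage("summarize", summarize_probes(m, ann, "gene"))
  exon_expr <- stage("summarize", summarize_probes(m, ann, "exon"))
  de <- stage("de", select_de(
    gene_expr, presence,
    numerator = dcfg$numerator, denominator = dcfg$denominator,
    ratio_low = dcfg$ratio_low %||% 0.75,
    ratio_high = dcfg$ratio_high %||% 1.33,
    alpha = dcfg$alpha %||% 0.05, center = dcfg$center %||% "mean"))

  acfg <- config$arh %||% list()
  arh <- stage("arh", {
    profile <- exon_ratio_profile(exon_expr, models,
                                  numerator = dcfg$numerator,
                                  denominator = dcfg$denominator,
                                  center = dcfg$center %||% "mean")
    scores <- arh_score(profile)
    scores <- arh_pvalue(scores, profile, B = acfg$resamples %||% 10000,
                         seed = seed + 1L,
                         min_exons = acfg$min_exons %||% 3,
                         alpha = acfg$alpha %||% 0.05)
    profile <- flag_exons(profile, scores,
                          multiplier = acfg$exon_flag_multiplier %||% 2)
    list(profile = profile, scores = scores)
  })

  overlap <- stage("overlap", overlap_de_as(de, arh$scores))
  tcfg <- config$top %||% list()
  tops <- stage("top", top_table(de, low = tcfg$low %||% -1.5,
                                 high = tcfg$high %||% 1.2))

  qtl_tab <- NULL
  if (!is.null(config$qtl)) {
    qtl_tab <- stage("qtl", {
      qtls <- read_qtl_intervals(resolve_path(config$qtl$path, config),
                                 bed = isTRUE(config$qtl$bed))
      loci <- if (!is.null(config$qtl$loci))
        read_gene_loci(resolve_path(config$qtl$loci, config),
                       bed = isTRUE(config$qtl$loci_bed))
      else gene_loci_from_models(models)
      qtl_overlap(loci, qtls, de, arh$scores)
    })
  }

  stage("write", {
    write_probe_matrix(m, file.path(outdir, "normalized_matrix.tsv"))
    write_tsv(as.data.frame(presence), file.path(outdir, "presence.tsv"))
    write_results(de, as_exon_table(arh$profile, arh$scores), outdir)
    sc <- arh$scores[order(arh$scores$p_value, -arh$scores$arh,
                           arh$scores$gene_id), ]
    write_tsv(sc, file.path(outdir, "as_genes.tsv"))
    ov <- data.frame(
      gene_id = c(overlap$de_only, overlap$as_only, overlap$both),
      category = rep(c("de_only", "as_only", "both"),
                     lengths(overlap)), stringsAsFactors = FALSE)
    write_tsv(ov, file.path(outdir, "overlap.tsv"))
    write_tsv(tops$low, file.path(outdir, "top_low.tsv"))
    write_tsv(tops$high, file.path(outdir, "top_high.tsv"))
    if (!is.null(qtl_tab))
      write_tsv(qtl_tab, file.path(outdir, "qtl_overlap.tsv"))
    if (!is.null(truth)) {
      write_tsv(truth, file.path(outdir, "truth.tsv"))
      write_tsv(truth_eval(truth, de, arh$scores),
                file.path(outdir, "metrics.tsv"))
    }
    cfg_file <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, cfg_file)
    manifest <- data.frame(
      key = c("config_md5", "seed", "package_version"),
      value = c(unname(tools::md5sum(cfg_file)), as.character(seed),
                as.character(utils::packageVersion("exonarh"))),
      stringsAsFactors = FALSE)
    unlink(cfg_file)
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  })

  invisible(list(matrix = m, presence = presence, de = de,
                 profile = arh$profile, scores = arh$scores,
                 overlap = overlap, top = tops, qtl = qtl_tab,
                 truth = truth))
}
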