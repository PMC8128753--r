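#' Read and validate a probe annotation table
#'
#' The annotation maps each probe to its exon and gene, carries the genomic
#' position of the exon, the probe's G+C base count (an integer, 0-25 for
#' 25-mers; GC matching against background probes is done on this discrete
#' class), and a flag marking background control probes -- probes with no
#' genomic target used to estimate nonspecific signal.
#'
#' Coordinates are 1-based inclusive internally (the Ensembl convention).
#' With `bed = TRUE` the positions are interpreted as BED-style 0-based
#' half-open intervals and converted on read.
#'
#' @param path TSV file (optionally gzipped) with header columns
#'   `probe_id`, `gene_id`, `exon_id`, `chrom`, `exon_start`, `exon_end`,
#'   `gc_count`, `is_background`.  `gene_id`/`exon_id` are empty for
#'   background probes.
#' @param bed logical; if `TRUE`, convert 0-based half-open coordinates to
#'   1-based inclusive.
#' @return A validated `data.frame` of class `probe_annotation`.
#' @export
read_probe_annotation <- function(path, bed = FALSE) {
  df <- read_tsv(path, colClasses = c(
    probe_id = "character", gene_id = "character", exon_id = "character",
    chrom = "character", exon_start = "integer", exon_end = "integer",
    gc_count = "integer", is_background = "logical"))
  required <- c("probe_id", "gene_id", "exon_id", "chrom", "exon_start",
                "exon_end", "gc_count", "is_background")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation file missing column(s): ", paste(missing, collapse = ", "))
  df$gene_id[is.na(df$gene_id)] <- ""
  df$exon_id[is.na(df$exon_id)] <- ""
  if (bed) df$exon_start <- df$exon_start + 1L
  probe_annotation(df)
}

#' Construct / validate a probe annotation
#'
#' @param df data.frame with the columns documented in
#'   [read_probe_annotation()].
#' @return `df` with class `probe_annotation`.
#' @export
probe_annotation <- function(df) {
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop("duplicate probe_id in annotation: ", paste(unique(dup), collapse = ", "))
  bad_bg <- !df$is_background & (df$gene_id == "" | df$exon_id == "")
  if (any(bad_bg))
    stop("non-background probe(s) without gene/exon assignment: ",
         paste(df$probe_id[bad_bg], collapse = ", "))
  bg_with_gene <- df$is_background & (df$gene_id != "" | df$exon_id != "")
  if (any(bg_with_gene))
    stop("background probe(s) carry a gene/exon assignment: ",
         paste(df$probe_id[bg_with_gene], collapse = ", "))
  bad_coord <- !df$is_background & df$exon_start > df$exon_end
  if (any(bad_coord))
    stop("exon_start > exon_end for probe(s): ",
         paste(df$probe_id[bad_coord], collapse = ", "))
  if (any(df$gc_count < 0))
    stop("negative gc_count for probe(s): ",
         paste(df$probe_id[df$gc_count < 0], collapse = ", "))
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Write a probe annotation table
#'
#' @param ann a `probe_annotation`.
#' @param path output TSV path (`.gz` for gzip).
#' @export
write_probe_annotation <- function(ann, path) {
  write_tsv(as.data.frame(ann), path)
}

#' Assemble gene models from an annotation
#'
#' One row per exon, ordered within each gene by genomic position
#' (chromosome, then exon start); strand is ignored.  `exon_index` is the
#' 1-based genomic order used when plotting exon expression profiles.
#'
#' @param ann a `probe_annotation`.
#' @return data.frame with `gene_id`, `exon_id`, `chrom`, `exon_start`,
#'   `exon_end`, `exon_index`, `n_probes`.
#' @export
gene_models <- function(ann) {
  g <- ann[!ann$is_background, , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(gene_id = character(), exon_id = character(),
                      chrom = character(), exon_start = integer(),
                      exon_end = integer(), exon_index = integer(),
                      n_probes = integer()))
  }
  ex <- unique(g[, c("gene_id", "exon_id", "chrom", "exon_start", "exon_end")])
  dup_ex <- ex$exon_id[duplicated(paste(ex$gene_id, ex$exon_id))]
  if (length(dup_ex))
    stop("exon(s) with inconsistent coordinates: ", paste(dup_ex, collapse = ", "))
  ex <- ex[order(ex$gene_id, ex$chrom, ex$exon_start, ex$exon_id), ]
  ex$exon_index <- stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along)
  np <- table(paste(g$gene_id, g$exon_id, sep = "\r"))
  ex$n_probes <- as.integer(np[paste(ex$gene_id, ex$exon_id, sep = "\r")])
  rownames(ex) <- NULL
  ex
}

#' Construct a probe x sample matrix of log2 intensities
#'
#' @param values numeric matrix, rows = probes (rownames required),
#'   columns = samples (colnames required); log2 scale.
#' @param conditions named character vector mapping sample id to condition
#'   label; exactly two distinct labels.
#' @return object of class `probe_matrix`: list with `values` and
#'   `conditions`.
#' @export
probe_matrix <- function(values, conditions) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("probe matrix needs probe rownames and sample colnames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("probe matrix contains non-finite values")
  conditions <- conditions[colnames(values)]
  if (anyNA(conditions))
    stop("sample(s) missing from condition map: ",
         paste(setdiff(colnames(values), names(conditions)), collapse = ", "))
  if (length(unique(conditions)) != 2L)
    stop("exactly two condition labels required, got: ",
         paste(unique(conditions), collapse = ", "))
  structure(list(values = values, conditions = conditions),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples (log2)\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$conditions)),
                                   table(x$conditions)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a probe intensity matrix
#'
#' @param path TSV (optionally gzipped): first column `probe_id`, remaining
#'   columns one per sample.
#' @param condition_map named character vector, sample id -> condition label
#'   (exactly two labels).  Samples absent from the map are dropped.
#' @param log2_input if `FALSE` (default) the file holds raw intensities
#'   (must be > 0) and is log2-transformed on read; if `TRUE` values are
#'   already log2.
#' @return a [probe_matrix()].
#' @export
read_probe_matrix <- function(path, condition_map, log2_input = FALSE) {
  df <- read_tsv(path)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id")
  samples <- names(condition_map)
  missing <- setdiff(samples, names(df))
  if (length(missing))
    stop("sample(s) in condition map missing from file: ",
         paste(missing, collapse = ", "))
  m <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  if (!log2_input) {
    if (any(m <= 0))
      stop("non-positive raw intensity; supply log2_input = TRUE for log2 data")
    m <- log2(m)
  }
  probe_matrix(m, condition_map)
}

#' Write a probe matrix
#'
#' @param m a `probe_matrix` (values written on log2 scale).
#' @param path output TSV path.
#' @export
write_probe_matrix <- function(m, path) {
  df <- data.frame(probe_id = rownames(m$values), m$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a QTL interval table
#'
#' Expected columns: `name`, `chrom`, `marker_pos_mb`, `window_mb`,
#' `phenotypes` (free text).  Megabase positions are converted to bp.
#' With `bed = TRUE` a BED file (chrom, start, end, name) is read instead
#' and the marker placed at the interval midpoint.
#'
#' @param path TSV or BED file.
#' @param bed logical.
#' @return data.frame `name`, `chrom`, `marker_pos`, `window`, `phenotypes`.
#' @export
read_qtl_intervals <- function(path, bed = FALSE) {
  if (bed) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:4] <- c("chrom", "start", "end", "name")
    out <- data.frame(
      name = df$name, chrom = df$chrom,
      marker_pos = as.integer(round((df$start + 1 + df$end) / 2)),
      window = as.integer(ceiling((df$end - df$start) / 2)),
      phenotypes = "", stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path)
    out <- data.frame(
      name = df$name, chrom = df$chrom,
      marker_pos = as.integer(round(df$marker_pos_mb * 1e6)),
      window = as.integer(round(df$window_mb * 1e6)),
      phenotypes = df$phenotypes %||% "", stringsAsFactors = FALSE)
  }
  if (any(out$marker_pos <= 0)) stop("marker_pos must be positive")
  if (any(out$window <= 0)) stop("window must be positive")
  out
}

#' Read a gene coordinate table
#'
#' @param path TSV with `gene_id`, `chrom`, `start`, `end` (bp, 1-based
#'   inclusive) or, with `bed = TRUE`, a BED file (chrom, start, end, gene_id).
#' @param bed logical.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_loci <- function(path, bed = FALSE) {
  if (bed) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(gene_id = df[[4]], chrom = df[[1]],
                      start = as.integer(df[[2]] + 1L),
                      end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path)
    out <- df[, c("gene_id", "chrom", "start", "end")]
    out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  }
  if (any(out$start > out$end)) stop("gene locus with start > end")
  out
}

#' Write differential-expression and alternative-splicing result tables
#'
#' Emits `de_genes.tsv` (one row per gene, sorted by Wilcoxon p then
#' gene id) and `as_exons.tsv` (one row per exon of every tested gene,
#' sorted by gene ARH p, gene id, then genomic exon order).  Row order is
#' deterministic so identical analyses produce byte-identical files.
#'
#' @param de DE result table from [select_de()] (may have zero rows).
#' @param as_exons exon-level AS table from [as_exon_table()] (may have
#'   zero rows).
#' @param outdir output directory, created if needed.
#' @return invisible character vector of file paths.
#' @export
write_results <- function(de, as_exons, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  de_path <- file.path(outdir, "de_genes.tsv")
  as_path <- file.path(outdir, "as_exons.tsv")
  de_o <- de[order(de$wilcoxon_p, de$gene_id), , drop = FALSE]
  write_tsv(de_o, de_path)
  as_o <- as_exons[order(as_exons$gene_p, as_exons$gene_id,
                         as_exons$exon_index), , drop = FALSE]
  write_tsv(as_o, as_path)
  invisible(c(de_path, as_path))
}
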