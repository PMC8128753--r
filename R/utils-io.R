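#' @importFrom utils read.delim write.table
NULL

# TSV helpers shared by every table reader/writer.  Numeric columns are
# written with 17 significant digits so that write -> read is the identity
# for doubles (and write -> read -> write is byte-identical).  Paths ending
# in .gz are compressed transparently; gzipped inputs are auto-detected by
# base connections.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
    if (is.logical(df2[[j]])) df2[[j]] <- ifelse(df2[[j]], "TRUE", "FALSE")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- c(
    paste(names(df2), collapse = "\t"),
    if (nrow(df2)) do.call(paste, c(unname(df2), sep = "\t"))
  )
  writeLines(lines, con)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  read.delim(path, header = TRUE, sep = "\t", colClasses = colClasses,
             stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
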