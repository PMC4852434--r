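#' Read and write expression matrices as tab-separated text
#'
#' The on-disk layout is a (optionally gzip-compressed) TSV with a header
#' row, the first column named `gene_id`, and one column per sample.
#' Population labels travel in an optional sidecar (see `groups`).
#'
#' @param path file path; a `.gz` suffix triggers gzip compression.
#' @param x an [expression_matrix()].
#' @param groups optional named character vector of sample group labels used
#'   when reading; writing stores values only.
#' @param scale scale flag to stamp on the matrix when reading.
#' @return `read_expression_tsv` returns an `ExpressionMatrix`;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  x <- as_em(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, groups = NULL,
                                scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("expected first column 'gene_id' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m, groups = groups, scale = scale)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member gene IDs, all
#' tab-separated. Lines with no members after parsing are reported and
#' skipped on read.
#'
#' @param path file path.
#' @param collection a [gene_set_collection()].
#' @return `read_gmt` returns a `GeneSetCollection`; `write_gmt` returns
#'   `path` invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, " in ", path,
                            ": fewer than 3 fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("GMT line ", i, " ('", f[1], "') has no members; skipped")
      next
    }
    sets[[length(sets) + 1L]] <- gene_set(f[1], members, f[2])
  }
  gene_set_collection(sets, source = path)
}

#' Read and write per-cell QC metric tables
#'
#' Columns: `sample_id`, `reads`, `unique_map_rate`, `exonic_rate`,
#' `detected_genes`, `population`.
#'
#' @param qc a QC data frame as produced by [generate_qc_table()].
#' @param path file path.
#' @return `read_qc_tsv` returns the data frame; `write_qc_tsv` returns
#'   `path` invisibly.
#' @export
write_qc_tsv <- function(qc, path) {
  write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qc_tsv
#' @export
read_qc_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "reads", "unique_map_rate", "exonic_rate",
            "detected_genes", "population")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("QC table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  df
}
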