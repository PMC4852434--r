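#' Filter cells on sequencing QC thresholds
#'
#' A cell passes iff all four criteria hold strictly: reads > 1,000,000;
#' uniquely-mapped rate > 0.60; exonic coverage rate > 0.35; detected genes
#' > 5000. The inequalities are strict, so a cell sitting exactly on a
#' threshold fails.
#'
#' @param qc data frame with columns `sample_id`, `reads`,
#'   `unique_map_rate`, `exonic_rate`, `detected_genes` and optionally
#'   `population`.
#' @param min_reads,min_unique_map_rate,min_exonic_rate,min_detected_genes
#'   the (strict) thresholds.
#' @return list with `passing` (character vector of passing sample IDs, in
#'   input order), `report` (named integer vector of per-criterion failure
#'   counts; a cell can fail several), and `table` (the input annotated with
#'   a logical `pass` column).
#' @export
filter_cells <- function(qc, min_reads = 1e6, min_unique_map_rate = 0.60,
                         min_exonic_rate = 0.35,
                         min_detected_genes = 5000) {
  need <- c("sample_id", "reads", "unique_map_rate", "exonic_rate",
            "detected_genes")
  missing <- setdiff(need, names(qc))
  if (length(missing))
    stop("QC table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(qc$sample_id))
    stop("duplicate sample_id in QC table: ",
         paste(unique(qc$sample_id[duplicated(qc$sample_id)]),
               collapse = ", "))
  if (any(qc$unique_map_rate < 0 | qc$unique_map_rate > 1) ||
      any(qc$exonic_rate < 0 | qc$exonic_rate > 1))
    stop("mapping-rate fractions must lie in [0, 1]")
  if (any(qc$reads < 0) || any(qc$detected_genes < 0))
    stop("read and gene counts must be non-negative")
  fail <- cbind(reads = !(qc$reads > min_reads),
                unique_map_rate = !(qc$unique_map_rate >
                                      min_unique_map_rate),
                exonic_rate = !(qc$exonic_rate > min_exonic_rate),
                detected_genes = !(qc$detected_genes > min_detected_genes))
  pass <- rowSums(fail) == 0
  out <- qc
  out$pass <- pass
  list(passing = qc$sample_id[pass],
       report = colSums(fail),
       table = out)
}

#' Filter genes on detection across population groups
#'
#' A gene is detected in a sample when its TPM exceeds `tpm_threshold`
#' (strictly). A gene is kept iff, in at least one population group, the
#' fraction of detected samples exceeds `group_fraction` (strictly). Row
#' order is preserved; reapplying the filter is the identity.
#'
#' @param x `ExpressionMatrix` on linear TPM scale with group labels.
#' @param tpm_threshold detection threshold on TPM (default 1).
#' @param group_fraction minimum (strict) detected fraction within a group
#'   (default 0.10).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_genes_by_detection <- function(x, tpm_threshold = 1,
                                      group_fraction = 0.10) {
  x <- as_em(x)
  if (x$scale != "tpm")
    stop("detection filtering requires the linear TPM scale")
  if (is.null(x$groups))
    stop("sample group labels are required for detection filtering")
  groups <- unique(x$groups)
  keep <- rep(FALSE, nrow(x$values))
  for (g in groups) {
    cols <- which(x$groups == g)
    if (!length(cols)) stop("empty group: ", g)
    frac <- rowMeans(x$values[, cols, drop = FALSE] > tpm_threshold)
    keep <- keep | (frac > group_fraction)
  }
  expression_matrix(x$values[keep, , drop = FALSE], groups = x$groups,
                    scale = "tpm")
}

#' Log-transform an expression matrix
#'
#' Replaces linear TPM values by `log2(TPM + 1)` and flips the scale flag.
#'
#' @param x `ExpressionMatrix` on linear TPM scale.
#' @return `ExpressionMatrix` on the log2 scale.
#' @export
log_transform <- function(x) {
  x <- as_em(x)
  if (x$scale == "log2")
    stop("matrix is already on the log2 scale")
  expression_matrix(log2(x$values + 1), groups = x$groups, scale = "log2")
}

#' Mean-centroid normalization of sample-to-sample variation
#'
#' Shifts each sample by a constant so that every sample's mean over genes
#' equals the grand mean over all samples. Within-sample relative
#' differences between genes are untouched.
#'
#' @param x `ExpressionMatrix` on the log2 scale.
#' @return The normalized `ExpressionMatrix`.
#' @export
mean_centroid_normalize <- function(x) {
  x <- as_em(x, scale = "log2")
  if (x$scale != "log2")
    stop("mean-centroid normalization expects the log2 scale")
  sample_means <- colMeans(x$values)
  shifted <- sweep(x$values, 2, sample_means - mean(sample_means))
  out <- x
  out$values <- shifted
  out
}

#' Per-gene coefficient of variation within a group
#'
#' CV = sample standard deviation / mean of linear TPM over the group's
#' samples. Genes with zero mean have no defined CV and are returned as
#' `NA`.
#'
#' @param x `ExpressionMatrix` on linear TPM scale.
#' @param group population label (requires group labels) or a character
#'   vector of sample IDs.
#' @return named numeric vector of per-gene CVs (`NA` where undefined).
#' @export
gene_cv <- function(x, group) {
  x <- as_em(x)
  if (x$scale != "tpm")
    stop("CV is defined on the linear TPM scale")
  cols <- if (length(group) == 1 && !is.null(x$groups) &&
              group %in% x$groups) {
    which(x$groups == group)
  } else {
    match(group, colnames(x$values))
  }
  if (anyNA(cols) || !length(cols))
    stop("group selects no samples")
  if (length(cols) < 2)
    stop("CV needs at least 2 samples (sd undefined for n = 1)")
  v <- x$values[, cols, drop = FALSE]
  mu <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  names(cv) <- rownames(x$values)
  cv
}

#' Differential expression between two groups
#'
#' Per-gene two-sided Student's t-test (equal variance by default; Welch
#' behind `var_equal = FALSE`) on `log2(TPM + 1)` values, with
#' Benjamini-Hochberg adjustment over all tested genes. Fold change is
#' computed on the linear TPM scale as `(meanA + pseudocount) /
#' (meanB + pseudocount)`. A gene is significant when FDR < `fdr_cutoff`
#' and the fold change is at least `fc_cutoff` in either direction.
#'
#' @param x `ExpressionMatrix` on linear TPM scale.
#' @param group_a,group_b population labels or sample-ID vectors; both need
#'   at least two samples.
#' @param fdr_cutoff,fc_cutoff significance thresholds (defaults 0.01, 2).
#' @param pseudocount added to linear group means before the ratio
#'   (default 1).
#' @param var_equal pooled-variance Student's t when `TRUE` (default),
#'   Welch otherwise.
#' @return data frame (one row per gene): `gene_id`, `mean_a`, `mean_b`
#'   (linear TPM), `fc`, `t_stat`, `p_value`, `fdr`, `is_significant`.
#' @export
differential_expression <- function(x, group_a, group_b, fdr_cutoff = 0.01,
                                    fc_cutoff = 2, pseudocount = 1,
                                    var_equal = TRUE) {
  x <- as_em(x)
  if (x$scale != "tpm")
    stop("supply linear TPM; log values are taken internally for the test")
  pick <- function(g) {
    cols <- if (length(g) == 1 && !is.null(x$groups) && g %in% x$groups)
      which(x$groups == g) else match(g, colnames(x$values))
    if (anyNA(cols) || length(cols) < 2)
      stop("each group needs >= 2 matched samples")
    cols
  }
  ca <- pick(group_a); cb <- pick(group_b)
  va <- x$values[, ca, drop = FALSE]; vb <- x$values[, cb, drop = FALSE]
  la <- log2(va + 1); lb <- log2(vb + 1)
  stat <- t(vapply(seq_len(nrow(la)), function(i) {
    a <- la[i, ]; b <- lb[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate gene: no within-group variance
      if (mean(a) == mean(b)) c(0, 1) else c(Inf * sign(mean(a) - mean(b)),
                                             0)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
      c(unname(tt$statistic), tt$p.value)
    }
  }, numeric(2)))
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  fc <- (mean_a + pseudocount) / (mean_b + pseudocount)
  fdr <- stats::p.adjust(stat[, 2], method = "BH")
  data.frame(gene_id = rownames(x$values), mean_a = mean_a, mean_b = mean_b,
             fc = fc, t_stat = stat[, 1], p_value = stat[, 2], fdr = fdr,
             is_significant = fdr < fdr_cutoff &
               (fc >= fc_cutoff | fc <= 1 / fc_cutoff),
             row.names = NULL)
}

#' Explanatory power of pooled single cells for the bulk profile
#'
#' For each pool size k, repeatedly samples k cells without replacement,
#' regresses the bulk profile on the k cell profiles (ordinary least
#' squares over genes, with intercept) and records the adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - k - 1)` with n = number of genes.
#'
#' @param bulk numeric vector (or one-column matrix) of the bulk profile
#'   over genes, log2 scale.
#' @param cells `ExpressionMatrix` (log2 scale) or numeric matrix of
#'   single-cell profiles sharing the bulk's gene index.
#' @param pool_sizes integer vector of pool sizes k; each must satisfy
#'   k < n_genes - 1.
#' @param n_permutations random pools per k (default 1000).
#' @param seed RNG seed recorded in the result.
#' @return object of class `PooledRegressionResult`: list with `pool_sizes`,
#'   `adj_r2` (list of per-permutation values per k), `mean_adj_r2`,
#'   `n_permutations`, `seed`.
#' @export
pooled_cell_regression <- function(bulk, cells, pool_sizes,
                                   n_permutations = 1000, seed = 1) {
  m <- if (is_expression_matrix(cells)) cells$values else cells
  bulk <- as.numeric(bulk)
  if (length(bulk) != nrow(m))
    stop("bulk profile and cell matrix must share the gene index")
  n_genes <- nrow(m); n_cells <- ncol(m)
  pool_sizes <- as.integer(pool_sizes)
  if (any(pool_sizes < 1) || any(pool_sizes > n_cells))
    stop("pool sizes must be between 1 and the number of cells")
  if (any(pool_sizes >= n_genes - 1))
    stop("pool size k must satisfy k < n_genes - 1 ",
         "(adjusted R-squared undefined otherwise)")
  stopifnot(n_permutations > 0)
  set.seed(seed)
  tss <- sum((bulk - mean(bulk))^2)
  adj <- lapply(pool_sizes, function(k) {
    vapply(seq_len(n_permutations), function(i) {
      cols <- sample.int(n_cells, k)
      fit <- stats::lm.fit(cbind(1, m[, cols, drop = FALSE]), bulk)
      r2 <- 1 - sum(fit$residuals^2) / tss
      1 - (1 - r2) * (n_genes - 1) / (n_genes - k - 1)
    }, 0)
  })
  names(adj) <- as.character(pool_sizes)
  structure(list(pool_sizes = pool_sizes, adj_r2 = adj,
                 mean_adj_r2 = vapply(adj, mean, 0),
                 n_permutations = n_permutations, seed = seed),
            class = "PooledRegressionResult")
}

#' @export
print.PooledRegressionResult <- function(x, ...) {
  cat("Pooled single-cell regression (", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  print(data.frame(k = x$pool_sizes, mean_adj_r2 = x$mean_adj_r2,
                   row.names = NULL))
  invisible(x)
}
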