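qc_record <- function(id, reads, umr, exo, genes, pop = "tumor") {
  data.frame(sample_id = id, reads = reads, unique_map_rate = umr,
             exonic_rate = exo, detected_genes = genes, population = pop)
}

test_that("cell QC thresholds are strict on every criterion", {
  qc <- rbind(
    qc_record("pass", 1.2e6, 0.65, 0.40, 6000),
    qc_record("reads_at_boundary", 1e6, 0.99, 0.99, 9000),
    qc_record("umr_at_boundary", 2e6, 0.60, 0.50, 6000),
    qc_record("exonic_at_boundary", 2e6, 0.80, 0.35, 6000),
    qc_record("genes_at_boundary", 2e6, 0.80, 0.50, 5000),
    qc_record("all_zero", 0, 0, 0, 0))
  res <- filter_cells(qc)
  expect_identical(res$passing, "pass")
  # the all-zero record fails all four criteria at once
  expect_equal(unname(res$report),
               c(2, 2, 2, 2))
  expect_error(filter_cells(rbind(qc, qc_record("pass", 2e6, .8, .5,
                                                6000))),
               "duplicate sample_id")
})

test_that("cell QC is order-invariant and idempotent", {
  cfg <- simulation_config(seed = 12,
                           n_cells_per_population = c(a = 30L, b = 30L),
                           subpopulation_design = list(
                             list(population = "a", fraction = 1,
                                  active = character()),
                             list(population = "b", fraction = 1,
                                  active = character())))
  qc <- generate_qc_table(cfg, pass_counts = c(a = 20, b = 10))
  res <- filter_cells(qc)
  shuffled <- qc[rev(seq_len(nrow(qc))), ]
  expect_setequal(filter_cells(shuffled)$passing, res$passing)
  again <- filter_cells(res$table[res$table$pass,
                                  setdiff(names(res$table), "pass")])
  expect_identical(again$passing, res$passing)
})

test_that("gene detection filter applies the strict >10% of-a-group rule", {
  # 40 cells in one group: 5/40 = 12.5% detected is kept,
  # 4/40 = 10% exactly is removed, all-zero is removed
  m <- matrix(0, 3, 40,
              dimnames = list(c("kept", "boundary", "zero"),
                              sprintf("c%02d", 1:40)))
  m["kept", 1:5] <- 10
  m["boundary", 1:4] <- 10
  x <- expression_matrix(m, groups = setNames(rep("g", 40),
                                              colnames(m)))
  f <- filter_genes_by_detection(x)
  expect_identical(rownames(f$values), "kept")
  # a submatrix: reapplying is the identity
  expect_identical(filter_genes_by_detection(f)$values, f$values)
  # detection means TPM strictly greater than the threshold
  m2 <- m; m2["boundary", 1:30] <- 1  # TPM exactly 1 is not detected
  f2 <- filter_genes_by_detection(expression_matrix(
    m2, groups = setNames(rep("g", 40), colnames(m2))))
  expect_false("boundary" %in% rownames(f2$values))
})

test_that("log transform maps TPM through log2(TPM + 1) once", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lx <- log_transform(expression_matrix(m))
  expect_equal(lx$values[1, 1], 0)
  expect_equal(lx$values[2, 1], 1)
  expect_equal(lx$values[1, 2], 3)  # log2(8)
  expect_identical(lx$scale, "log2")
  expect_error(log_transform(lx), "already")
})

test_that("mean-centroid normalization equalizes per-sample means", {
  m <- matrix(c(4, 6, 6, 8), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  x <- expression_matrix(m, scale = "log2")
  nx <- mean_centroid_normalize(x)
  expect_equal(unname(colMeans(nx$values)), c(6, 6))
  # within-sample differences preserved
  expect_equal(diff(nx$values[, 1]), diff(m[, 1]), ignore_attr = TRUE)
  # identity when already equal; exact post-condition on a random matrix
  expect_equal(mean_centroid_normalize(nx)$values, nx$values)
  r <- expression_matrix(matrix(rnorm(500), 50, 10,
                                dimnames = list(paste0("g", 1:50),
                                                paste0("s", 1:10))),
                         scale = "log2")
  cm <- colMeans(mean_centroid_normalize(r)$values)
  expect_lt(max(cm) - min(cm), 1e-9)
})

test_that("coefficient of variation follows sd/mean with NA for zero mean", {
  m <- rbind(constant = c(5, 5), two_vals = c(1, 3), zero = c(0, 0))
  colnames(m) <- c("s1", "s2")
  cv <- gene_cv(expression_matrix(m), c("s1", "s2"))
  expect_equal(unname(cv["constant"]), 0)
  expect_equal(unname(cv["two_vals"]), sqrt(2) / 2, tolerance = 1e-12)
  expect_true(is.na(cv["zero"]))
  expect_error(gene_cv(expression_matrix(m), "s1"), "at least 2")
})

test_that("differential expression flags planted shifts and only those", {
  set.seed(21)
  p <- 200; n <- 30
  base <- matrix(2^rnorm(p * 2 * n, 6, 0.5), p, 2 * n,
                 dimnames = list(sprintf("g%03d", 1:p),
                                 sprintf("c%02d", 1:(2 * n))))
  shifted <- sprintf("g%03d", 1:20)
  base[shifted, 1:n] <- base[shifted, 1:n] * 4  # 2 log2 units
  x <- expression_matrix(base,
                         groups = setNames(rep(c("a", "b"), each = n),
                                           colnames(base)))
  deg <- differential_expression(x, "a", "b")
  expect_setequal(deg$gene_id[deg$is_significant], shifted)
  # symmetry: swapping groups inverts the fold change, keeps the flags
  deg_swap <- differential_expression(x, "b", "a")
  expect_equal(deg_swap$fc, 1 / deg$fc, tolerance = 1e-12)
  expect_identical(deg_swap$is_significant, deg$is_significant)
  expect_equal(deg_swap$p_value, deg$p_value, tolerance = 1e-12)
})

test_that("identical groups yield p = 1 and BH matches the hand example", {
  m <- matrix(2^rnorm(40, 5), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  m <- cbind(m, m); colnames(m) <- paste0("c", 1:8)
  x <- expression_matrix(m, groups = setNames(rep(c("a", "b"), each = 4),
                                              colnames(m)))
  deg <- differential_expression(x, "a", "b")
  expect_true(all(deg$p_value == 1))
  expect_false(any(deg$is_significant))
  # hand-applied BH step-up on (0.001, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(c(0.001, 0.02, 0.03, 0.04), "BH"),
               c(0.004, 0.04, 0.04, 0.04))
})

test_that("pooled-cell regression matches the adjusted R-squared contract", {
  cfg <- simulation_config(seed = 13, n_genes = 300L, dropout_rate = 0.2,
                           n_cells_per_population = c(tumor = 12L),
                           subpopulation_design = list(
                             list(population = "tumor", fraction = 1,
                                  active = "EGFR")))
  co <- generate_expression_cohort(cfg)
  cells <- log2(co$cells$values + 1)
  # bulk built as the exact mean of all cells: in the span of predictors
  bulk <- rowMeans(cells)
  res <- pooled_cell_regression(bulk, cells, pool_sizes = ncol(cells),
                                n_permutations = 5, seed = 2)
  expect_equal(unname(res$mean_adj_r2), 1, tolerance = 1e-9)
  # formula arithmetic: R2 = 0.5, n = 100, k = 2
  expect_equal(1 - 0.5 * 99 / 97, 0.4896907, tolerance = 1e-6)
  expect_error(pooled_cell_regression(bulk, cells,
                                      pool_sizes = nrow(cells)),
               "between 1 and")
  expect_error(pooled_cell_regression(bulk[1:10], cells[1:10, ],
                                      pool_sizes = 9), "k < n_genes")
})

test_that("pooled-cell explanatory power is non-decreasing in pool size", {
  cfg <- simulation_config(seed = 14, n_genes = 300L,
                           n_cells_per_population = c(tumor = 20L),
                           subpopulation_design = list(
                             list(population = "tumor", fraction = 0.5,
                                  active = "EGFR"),
                             list(population = "tumor", fraction = 0.5,
                                  active = "Src")))
  co <- generate_expression_cohort(cfg)
  cells <- log2(co$cells$values + 1)
  bulk <- log2(co$bulks$values[, 1] + 1)
  res <- pooled_cell_regression(bulk, cells, pool_sizes = c(1, 3, 6, 12),
                                n_permutations = 200, seed = 3)
  expect_true(all(diff(res$mean_adj_r2) > -0.01))
  # deterministic under the recorded seed
  res2 <- pooled_cell_regression(bulk, cells, pool_sizes = c(1, 3, 6, 12),
                                 n_permutations = 200, seed = 3)
  expect_identical(res$mean_adj_r2, res2$mean_adj_r2)
})
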