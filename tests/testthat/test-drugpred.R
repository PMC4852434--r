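test_that("location-scale batch adjustment removes planted effects exactly", {
  set.seed(91)
  p <- 60
  train <- matrix(rnorm(p * 20, 6), p, 20,
                  dimnames = list(sprintf("g%03d", 1:p),
                                  sprintf("s%02d", 1:20)))
  test <- train + 2  # the same samples offset by a constant batch shift
  colnames(test) <- sprintf("t%02d", 1:20)
  adj <- batch_adjust(train, test, mode = "location-scale")
  m <- adj$adjusted$values
  bm_train <- rowMeans(m[, adj$batch == "train"])
  bm_test <- rowMeans(m[, adj$batch == "test"])
  expect_lt(max(abs(bm_train - bm_test)), 1e-9)
  expect_equal(unname(adj$batch_effects$location), rep(2, p),
               tolerance = 1e-9)

  # identical batches: the transform is the identity to rounding error
  adj_id <- batch_adjust(train, train, mode = "location-scale")
  expect_lt(max(abs(adj_id$adjusted$values -
                      cbind(train, train))), 1e-9)
})

test_that("planted additive/multiplicative batch effects are recovered", {
  # synthetic cell-line panels generated with and without the batch
  # offsets; the only difference between them is the planted effect
  cfg_off <- simulation_config(seed = 15, n_genes = 200L,
                               gene_set_sizes = 20L,
                               n_cell_lines = 50L,
                               batch_offsets = list(
                                 cell_line = list(additive = 1.0,
                                                  multiplicative = 1.5)))
  cfg_clean <- simulation_config(seed = 15, n_genes = 200L,
                                 gene_set_sizes = 20L,
                                 n_cell_lines = 50L,
                                 batch_offsets = list(cell_line = NULL))
  with_off <- log2(generate_drug_training_set(cfg_off)$expr$values + 1)
  clean <- log2(generate_drug_training_set(cfg_clean)$expr$values + 1)
  colnames(clean) <- paste0(colnames(clean), "_b2")
  adj <- batch_adjust(with_off, clean, mode = "location-scale")
  # location = clean - offset batch: median across genes near -additive;
  # scale ratio near 1/multiplicative (log2(x+1) compresses slightly)
  expect_lt(abs(median(adj$batch_effects$location) + 1.0), 0.1)
  expect_lt(abs(median(adj$batch_effects$scale) - 1 / 1.5), 0.15 / 1.5)
  # and the adjustment removes what it estimated
  m <- adj$adjusted$values
  expect_lt(max(abs(rowMeans(m[, adj$batch == "train"]) -
                      rowMeans(m[, adj$batch == "test"]))), 1e-9)
})

test_that("empirical-Bayes mode aligns batch locations approximately", {
  skip_if_not_installed("sva")
  set.seed(92)
  p <- 80
  base <- matrix(rnorm(2 * p * 15, 6), p, 30,
                 dimnames = list(sprintf("g%03d", 1:p),
                                 sprintf("s%02d", 1:30)))
  train <- base[, 1:15]; test <- base[, 16:30] + 1.5
  adj <- batch_adjust(train, test, mode = "eb")
  m <- adj$adjusted$values
  gap <- rowMeans(m[, adj$batch == "test"]) -
    rowMeans(m[, adj$batch == "train"])
  expect_lt(median(abs(gap)), 0.2)  # shrinkage leaves small residuals
})

test_that("variance filter drops the exact low-variance quantile", {
  set.seed(93)
  m <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  m <- m * sqrt(1:10)  # variances approximately 1..10 by row
  f <- variance_filter(m, 0.20)
  expect_identical(rownames(f), paste0("g", 3:10))
  expect_identical(variance_filter(m, 0), m)
  # 7 genes at 20%: floor(1.4) = 1 gene removed
  f7 <- variance_filter(m[1:7, ], 0.20)
  expect_equal(nrow(f7), 6)
  expect_error(variance_filter(m, 1), "drop_fraction")
})

test_that("ridge closed form matches hand-computed and limiting cases", {
  # single predictor x = (1,2), y = (1,2), lambda = 1, no centering:
  # beta = x'y / (x'x + 1) = 5/6
  x <- matrix(c(1, 2), 1, 2, dimnames = list("g1", c("s1", "s2")))
  fit <- fit_ridge(x, c(1, 2), lambda = 1, center = FALSE)
  expect_equal(unname(fit$beta), 5 / 6, tolerance = 1e-12)

  # independent oracle: direct solve of (X'X + lambda I) beta = X'y
  set.seed(94)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  y <- rnorm(6)
  for (lam in c(0.5, 10)) {
    fit <- fit_ridge(X, y, lambda = lam)
    Xc <- scale(t(X), scale = FALSE)
    beta_direct <- solve(crossprod(Xc) + diag(lam, 30),
                         crossprod(Xc, y - mean(y)))
    expect_equal(unname(fit$beta), as.numeric(beta_direct),
                 tolerance = 1e-8)
  }

  # OLS limit on a full-rank system: beta converges to the generator
  set.seed(95)
  Xf <- matrix(rnorm(3 * 20), 3, 20,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
  beta_star <- c(1, -2, 0.5)
  yf <- drop(crossprod(Xf, beta_star))
  fit0 <- fit_ridge(Xf, yf, lambda = 1e-10, center = FALSE)
  expect_lt(max(abs(fit0$beta - beta_star)), 1e-6)

  # constant response: zero coefficients, intercept = the constant
  fitc <- fit_ridge(X, rep(3, 6), lambda = 1)
  expect_equal(unname(fitc$beta), rep(0, 30), tolerance = 1e-12)
  expect_equal(fitc$intercept, 3)
})

test_that("ridge predictions shrink to the training mean as lambda grows
           and ignore gene order", {
  set.seed(96)
  X <- matrix(rnorm(40 * 10, 5), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40),
                              paste0("s", 1:10)))
  y <- rnorm(10, 2)
  big <- fit_ridge(X, y, lambda = 1e8)
  pred <- predict_and_zscore(list(drug = big), X)
  expect_lt(max(abs(pred$predicted - mean(y))), 1e-3)

  lam_fit <- fit_ridge(X, y, lambda = 2)
  perm <- sample(40)
  lam_perm <- fit_ridge(X[perm, ], y, lambda = 2)
  p1 <- predict_and_zscore(list(d = lam_fit), X)$predicted
  p2 <- predict_and_zscore(list(d = lam_perm), X)$predicted
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("LOOCV recovers planted linear signal and stays null without it", {
  # effect_size 2 keeps the expression-to-activity readout well above the
  # gene-level noise so the noiseless response is the only error source
  cfg <- simulation_config(seed = 16, n_genes = 300L, n_cell_lines = 50L,
                           effect_size = 2, ic50_noise_sd = 0)
  tr <- generate_drug_training_set(cfg)
  X <- log2(tr$expr$values + 1)
  r <- loocv_evaluate(X, tr$response$afatinib)$r
  expect_gte(r, 0.99)

  # zero slope: held-out predictions carry no signal (fixed moderate
  # shrinkage; at extreme shrinkage every prediction collapses to the
  # fold mean, which is trivially anti-correlated with the held-out y)
  cfg0 <- simulation_config(seed = 16, n_genes = 300L,
                            n_cell_lines = 50L, ic50_slope = 0)
  tr0 <- generate_drug_training_set(cfg0)
  r0 <- loocv_evaluate(log2(tr0$expr$values + 1),
                       tr0$response$afatinib, lambda = 10)$r
  expect_lt(abs(r0), 0.3)

  # an exact 3-point line is reproduced perfectly
  x3 <- matrix(c(1, 2, 3), 1, 3,
               dimnames = list("g1", paste0("s", 1:3)))
  # perfect fit: base R warns that the ANOVA F is unreliable there
  expect_equal(suppressWarnings(
    loocv_evaluate(x3, c(1, 2, 3), lambda = 1e-8)$r), 1,
    tolerance = 1e-6)
})

test_that("prediction Z-scores follow the (x - mean)/sd contract", {
  x <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  model <- structure(list(beta = setNames(c(1, 0), c("g1", "g2")),
                          intercept = 0,
                          gene_ids = c("g1", "g2"),
                          gene_center = setNames(c(0, 0), c("g1", "g2")),
                          lambda = 1, centered = FALSE, n_train = 3),
                     class = "RidgeModel")
  pr <- predict_and_zscore(list(d = model), x)
  expect_equal(unname(pr$predicted["d", ]), c(1, 2, 3))
  expect_equal(unname(pr$z["d", ]), c(-1, 0, 1))
  # constant predictions: z undefined
  model$beta[] <- 0
  expect_true(all(is.na(predict_and_zscore(list(d = model), x)$z)))
  # missing genes are named in the error
  expect_error(predict_and_zscore(list(d = structure(
    list(beta = c(gX = 1), intercept = 0, gene_ids = "gX",
         gene_center = c(gX = 0)), class = "RidgeModel")), x), "gX")
  # affine invariance: shifting/scaling predictions leaves z unchanged
  shifted <- structure(list(beta = setNames(c(3, 0), c("g1", "g2")),
                            intercept = 7, gene_ids = c("g1", "g2"),
                            gene_center = setNames(c(0, 0),
                                                   c("g1", "g2"))),
                       class = "RidgeModel")
  expect_equal(predict_and_zscore(list(d = shifted), x)$z, pr$z)
})

test_that("measured IC50 Z-scoring works on the log10 nanomolar scale", {
  tab <- matrix(c(10, 100, 1000), 3, 1,
                dimnames = list(paste0("s", 1:3), "drugA"))
  z <- ic50_zscore(tab)
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  expect_true(all(is.na(ic50_zscore(matrix(c(5, 5, 5), 3, 1)))))
  expect_error(ic50_zscore(matrix(c(-1, 2), 2, 1)), "positive")
  expect_error(ic50_zscore(matrix(10, 1, 1)), "at least 2")
})

test_that("predicted-measured correlation handles exact and degenerate
           panels", {
  z <- matrix(c(1, 2, 3, -1, 0, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("s1", "s2", "s3")))
  res <- suppressWarnings(correlate_pred_measured(z, z))
  expect_equal(res$r, 1, tolerance = 1e-12)
  anti <- z; anti["d1", ] <- rev(z["d1", ]); anti["d2", ] <- rev(z["d2", ])
  res2 <- suppressWarnings(
    correlate_pred_measured(z[1, , drop = FALSE],
                            anti[1, , drop = FALSE]))
  expect_equal(res2$r, -1, tolerance = 1e-12)
  expect_error(correlate_pred_measured(z[, 1, drop = FALSE],
                                       z[, 1, drop = FALSE]),
               "fewer than 3")
})
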