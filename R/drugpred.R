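#' Batch adjustment of test samples onto a training panel
#'
#' Removes per-batch per-gene location and scale effects on the shared
#' genes so cell-line training expression and study samples are
#' comparable. In `"location-scale"` mode each gene is standardized on the
#' pooled data, per-batch means and scales are estimated by maximum
#' likelihood and removed exactly (post-adjustment per-gene batch means
#' are equal to numerical precision). In `"eb"` mode the per-gene batch
#' effects are shrunk across genes by the parametric empirical-Bayes
#' scheme of ComBat (via the sva package).
#'
#' @param train_x,test_x `ExpressionMatrix` objects (or matrices) on the
#'   log2 scale; genes are intersected.
#' @param mode `"eb"` (default) or `"location-scale"`.
#' @return list with `adjusted` (`ExpressionMatrix`, log2, training
#'   columns first), `batch` (named factor), and `batch_effects`: per-gene
#'   `location` differences and `scale` ratios of the test batch relative
#'   to the training batch, in log2 units (location-scale mode only).
#' @export
batch_adjust <- function(train_x, test_x,
                         mode = c("eb", "location-scale")) {
  mode <- match.arg(mode)
  tr <- if (is_expression_matrix(train_x)) train_x$values else train_x
  te <- if (is_expression_matrix(test_x)) test_x$values else test_x
  if (is_expression_matrix(train_x) && train_x$scale != "log2" ||
      is_expression_matrix(test_x) && test_x$scale != "log2")
    stop("batch adjustment expects log2-scale expression")
  shared <- intersect(rownames(tr), rownames(te))
  if (!length(shared)) stop("no shared genes between batches")
  if (ncol(tr) < 2 || ncol(te) < 2)
    stop("each batch needs at least 2 samples")
  comb <- cbind(tr[shared, , drop = FALSE], te[shared, , drop = FALSE])
  colnames(comb) <- make.unique(colnames(comb))
  batch <- factor(rep(c("train", "test"), c(ncol(tr), ncol(te))),
                  levels = c("train", "test"))
  names(batch) <- colnames(comb)

  mle_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  if (mode == "location-scale") {
    adj <- comb
    loc <- scl <- numeric(length(shared))
    for (i in seq_along(shared)) {
      v <- comb[i, ]
      g <- mean(v); s <- mle_sd(v)
      bm <- tapply(v, batch, mean)
      bs <- tapply(v, batch, mle_sd)
      if (s == 0) { loc[i] <- 0; scl[i] <- 1; next }
      z <- (v - g) / s
      for (b in levels(batch)) {
        idx <- batch == b
        zb <- z[idx] - mean(z[idx])
        sb <- mle_sd(z[idx])
        # zero within-batch variance: adjust location only
        z[idx] <- if (sb > 0) zb / sb else zb
      }
      adj[i, ] <- g + s * z
      loc[i] <- bm[["test"]] - bm[["train"]]
      scl[i] <- if (bs[["train"]] > 0) bs[["test"]] / bs[["train"]] else NA
    }
    effects <- list(location = setNames(loc, shared),
                    scale = setNames(scl, shared))
  } else {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("mode = 'eb' requires the sva package; ",
           "use mode = 'location-scale' otherwise")
    keep <- apply(comb, 1, function(v) mle_sd(v) > 0)
    adj <- comb
    adj[keep, ] <- sva::ComBat(dat = comb[keep, , drop = FALSE],
                               batch = batch)
    # constant genes carry no batch information; left untouched
    effects <- NULL
  }
  list(adjusted = expression_matrix(adj, groups = setNames(
         as.character(batch), colnames(comb)), scale = "log2"),
       batch = batch, batch_effects = effects, mode = mode)
}

#' Remove the lowest-varying fraction of genes
#'
#' Genes are ranked by variance across all samples and the
#' `floor(drop_fraction * p)` lowest-variance genes are removed, ties
#' broken by gene index. Focuses downstream models on biological over
#' technical variability.
#'
#' @param x `ExpressionMatrix` or numeric matrix (any scale).
#' @param drop_fraction fraction of genes to drop, in `[0, 1)`
#'   (default 0.20).
#' @return The filtered object, same class as the input, original row
#'   order preserved.
#' @export
variance_filter <- function(x, drop_fraction = 0.20) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  m <- if (is_expression_matrix(x)) x$values else x
  if (nrow(m) < 5) stop("variance filtering needs at least 5 genes")
  ndrop <- floor(drop_fraction * nrow(m))
  if (ndrop == 0) return(x)
  v <- apply(m, 1, stats::var)
  drop_idx <- order(v, seq_len(nrow(m)))[seq_len(ndrop)]
  keep <- sort(setdiff(seq_len(nrow(m)), drop_idx))
  if (is_expression_matrix(x))
    expression_matrix(m[keep, , drop = FALSE], groups = x$groups,
                      scale = x$scale)
  else m[keep, , drop = FALSE]
}

ridge_grid <- function() 10^seq(-4, 6, length.out = 21)

# Closed-form leave-one-out PRESS for ridge via the hat-matrix identity,
# computed from one SVD of the centered design.
ridge_loo_press <- function(sv, yc, lambda, n, add_intercept) {
  shrink <- sv$d^2 / (sv$d^2 + lambda)
  fitted <- sv$u %*% (shrink * crossprod(sv$u, yc))
  h <- rowSums(sweep(sv$u^2, 2, shrink, `*`)) +
    if (add_intercept) 1 / n else 0
  r <- (yc - fitted) / pmax(1 - h, 1e-12)
  sum(r^2)
}

#' Fit a ridge-regression drug-response model
#'
#' Solves `beta = (X'X + lambda I)^-1 X' y` on centered data (intercept =
#' mean response) through the singular-value decomposition, which is exact
#' for any number of genes, including p >> n. With `lambda = "auto"` the
#' shrinkage is chosen to minimize the closed-form leave-one-out error
#' over a logarithmic grid `10^-4 .. 10^6` (21 points); the selection is
#' deterministic.
#'
#' @param x genes x samples expression matrix (`ExpressionMatrix` on the
#'   log2 scale, or plain matrix).
#' @param y numeric response per sample (log10 IC50, nM); samples with
#'   missing response are dropped; at least 3 required.
#' @param lambda positive scalar or `"auto"`.
#' @param center center predictors and response (default `TRUE`, the
#'   standard model). `center = FALSE` fits through the origin with no
#'   intercept.
#' @return object of class `RidgeModel`: list with `beta` (named by gene),
#'   `intercept`, `lambda`, `gene_ids`, `gene_center`, `n_train`.
#' @export
fit_ridge <- function(x, y, lambda = "auto", center = TRUE) {
  m <- if (is_expression_matrix(x)) x$values else x
  if (length(y) != ncol(m))
    stop("response length must match the number of samples")
  ok <- !is.na(y)
  if (sum(ok) < 2)
    stop("need >= 2 samples with a measured response")
  m <- m[, ok, drop = FALSE]; y <- y[ok]
  X <- t(m)
  n <- nrow(X)
  if (center) {
    gene_center <- colMeans(X)
    Xc <- sweep(X, 2, gene_center)
    y_mean <- mean(y); yc <- y - y_mean
  } else {
    gene_center <- rep(0, ncol(X))
    Xc <- X; y_mean <- 0; yc <- y
  }
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  sv$d <- sv$d[pos]
  sv$u <- sv$u[, pos, drop = FALSE]
  sv$v <- sv$v[, pos, drop = FALSE]
  if (identical(lambda, "auto")) {
    press <- vapply(ridge_grid(), function(l)
      ridge_loo_press(sv, yc, l, n, center), 0)
    lambda <- ridge_grid()[which.min(press)]
  } else {
    lambda <- as.numeric(lambda)
    if (lambda < 0) stop("lambda must be non-negative")
    if (lambda == 0 && (length(sv$d) < ncol(Xc)))
      stop("design is singular at lambda = 0; choose lambda > 0")
  }
  beta <- sv$v %*% ((sv$d / (sv$d^2 + lambda)) * crossprod(sv$u, yc))
  beta <- setNames(as.numeric(beta), rownames(m))
  structure(list(beta = beta, intercept = y_mean, lambda = lambda,
                 gene_ids = rownames(m),
                 gene_center = setNames(gene_center, rownames(m)),
                 centered = center, n_train = n),
            class = "RidgeModel")
}

#' @export
print.RidgeModel <- function(x, ...) {
  cat(sprintf("RidgeModel: %d genes, lambda = %g, intercept = %.4g\n",
              length(x$beta), x$lambda, x$intercept))
  invisible(x)
}

predict_ridge <- function(model, m) {
  missing <- setdiff(model$gene_ids, rownames(m))
  if (length(missing))
    stop("test matrix lacks model genes: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)",
                                           length(missing) - 10))
  sub <- m[model$gene_ids, , drop = FALSE]
  drop(crossprod(sub - model$gene_center, model$beta)) + model$intercept
}

#' Leave-one-out cross-validation of a ridge drug model
#'
#' Each training sample is predicted by a model refit on all other
#' samples; accuracy is the Pearson correlation between held-out
#' predictions and measured responses, with the significance of the
#' linear fit assessed by one-way ANOVA.
#'
#' @param x genes x samples training expression.
#' @param y measured response per sample (log10 IC50, nM).
#' @param lambda shrinkage: a positive scalar, or `"auto"` to select once
#'   on the full data and hold fixed across folds.
#' @return list with `r` (Pearson, `NA` if the measured vector is
#'   constant), `p_value` (ANOVA of the regression fit), `predictions`
#'   (held-out, per sample) and `lambda`.
#' @export
loocv_evaluate <- function(x, y, lambda = "auto") {
  m <- if (is_expression_matrix(x)) x$values else x
  ok <- !is.na(y)
  if (sum(ok) < 3) stop("LOOCV needs >= 3 samples with responses")
  m <- m[, ok, drop = FALSE]; y <- y[ok]
  if (identical(lambda, "auto"))
    lambda <- fit_ridge(m, y, lambda = "auto")$lambda
  n <- ncol(m)
  preds <- vapply(seq_len(n), function(i) {
    fit <- fit_ridge(m[, -i, drop = FALSE], y[-i], lambda = lambda)
    predict_ridge(fit, m[, i, drop = FALSE])
  }, 0)
  names(preds) <- colnames(m)
  if (stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, predictions = preds,
                lambda = lambda,
                note = "measured response is constant; r undefined"))
  r <- stats::cor(preds, y)
  p <- if (stats::sd(preds) == 0) 1 else
    anova(stats::lm(y ~ preds))[["Pr(>F)"]][1]
  list(r = r, p_value = p, predictions = preds, lambda = lambda)
}

#' Predict drug sensitivity for test samples and Z-score per drug
#'
#' Applies fitted ridge models to test expression and transforms each
#' drug's predictions to Z-scores across the test samples
#' (`(yhat - mean) / sd`, sample sd). Lower Z means lower predicted IC50,
#' i.e. greater predicted sensitivity.
#'
#' @param models named list of [fit_ridge()] models, one per drug.
#' @param test_x genes x samples test expression (log2 scale, batch
#'   adjusted onto the training panel).
#' @return object of class `PredictionResult`: list with `predicted`
#'   (drugs x samples, raw log10 IC50 scale) and `z` (drugs x samples;
#'   `NA` when fewer than 2 samples or zero spread).
#' @export
predict_and_zscore <- function(models, test_x) {
  m <- if (is_expression_matrix(test_x)) test_x$values else test_x
  if (is.null(names(models)) || !all(nzchar(names(models))))
    stop("`models` must be a named list (drug labels)")
  pred <- t(vapply(models, function(mod) predict_ridge(mod, m),
                   numeric(ncol(m))))
  dimnames(pred) <- list(names(models), colnames(m))
  z <- pred * NA_real_
  if (ncol(pred) >= 2) {
    for (d in seq_len(nrow(pred))) {
      s <- stats::sd(pred[d, ])
      if (s > 0) z[d, ] <- (pred[d, ] - mean(pred[d, ])) / s
    }
  }
  structure(list(predicted = pred, z = z,
                 groups = if (is_expression_matrix(test_x)) test_x$groups
                          else NULL),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("PredictionResult: %d drugs x %d samples\n",
              nrow(x$predicted), ncol(x$predicted)))
  invisible(x)
}

#' Z-score measured IC50 values per drug
#'
#' Transforms nanomolar IC50 measurements to per-drug Z-scores across
#' samples, after a log10 transform (IC50s span orders of magnitude; the
#' log keeps single extreme values from dominating; disable with
#' `log10 = FALSE`).
#'
#' @param ic50 samples x drugs table (matrix or data frame) of IC50 in nM;
#'   all values must be positive; at least 2 samples.
#' @param log10 apply log10 before Z-scoring (default `TRUE`).
#' @return samples x drugs matrix of Z-scores (`NA` for a drug with zero
#'   spread).
#' @export
ic50_zscore <- function(ic50, log10 = TRUE) {
  m <- as.matrix(ic50)
  if (nrow(m) < 2) stop("Z-scoring needs at least 2 samples per drug")
  if (any(m <= 0, na.rm = TRUE))
    stop("IC50 values must be positive (nM)")
  if (log10) m <- log10(m)
  apply(m, 2, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(NA_real_, length(v))
    else (v - mean(v, na.rm = TRUE)) / s
  })
}

#' Correlate predicted and measured drug sensitivity
#'
#' Matches predicted and measured Z-scores on shared drugs and samples and
#' reports, per population (or overall), the Pearson correlation, the
#' linear fit, and the one-way ANOVA p-value of the regression.
#'
#' @param predicted drugs x samples matrix of predicted Z-scores (e.g.
#'   `$z` of a `PredictionResult`).
#' @param measured drugs x samples matrix of measured Z-scores on the same
#'   labels (transpose of [ic50_zscore()] output).
#' @param populations optional named vector sample -> population; when
#'   given, statistics are emitted per population.
#' @return data frame with columns `population`, `n`, `r`, `slope`,
#'   `intercept`, `p_value`.
#' @export
correlate_pred_measured <- function(predicted, measured,
                                    populations = NULL) {
  drugs <- intersect(rownames(predicted), rownames(measured))
  samples <- intersect(colnames(predicted), colnames(measured))
  if (!length(drugs) || !length(samples))
    stop("no matched drugs/samples between predicted and measured")
  pops <- if (is.null(populations))
    setNames(rep("all", length(samples)), samples)
  else populations[samples]
  out <- lapply(unique(pops), function(pop) {
    cols <- samples[pops == pop]
    xp <- as.numeric(predicted[drugs, cols])
    xm <- as.numeric(measured[drugs, cols])
    ok <- stats::complete.cases(xp, xm)
    if (sum(ok) < 3)
      stop("fewer than 3 matched points for population '", pop, "'")
    fit <- stats::lm(xm[ok] ~ xp[ok])
    data.frame(population = pop, n = sum(ok),
               r = stats::cor(xp[ok], xm[ok]),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               p_value = anova(fit)[["Pr(>F)"]][1])
  })
  do.call(rbind, out)
}
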