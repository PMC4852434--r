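# Independent oracles and small fixture builders shared across tests.

# Brute-force enrichment walk: a direct double loop over the rank list,
# written against the scoring definition and kept independent of the
# package's compiled implementation.
brute_force_walk <- function(expr_log2, members, sample_j, tau = 1,
                             variant = "max-deviation") {
  p <- nrow(expr_log2)
  n <- ncol(expr_log2)
  # kernel CDF per gene, plain loops
  fhat <- numeric(p)
  for (i in seq_len(p)) {
    s <- sd(expr_log2[i, ])
    h <- max(s / 4, 1e-6)
    acc <- 0
    for (m in seq_len(n))
      acc <- acc + pnorm((expr_log2[i, sample_j] - expr_log2[i, m]) / h)
    fhat[i] <- acc / n
  }
  ord <- order(-fhat, seq_len(p))
  rank_of <- integer(p); rank_of[ord] <- seq_len(p)
  r <- abs(p / 2 - rank_of)
  inset <- rownames(expr_log2) %in% members
  m_in <- sum(inset)
  stopifnot(m_in >= 1, m_in < p)
  sum_in <- sum(r[inset]^tau)
  nu <- numeric(p)
  run <- 0
  for (l in seq_len(p)) {
    g <- ord[l]
    inc <- if (sum_in > 0) r[g]^tau / sum_in else 1 / m_in
    run <- if (inset[g]) run + inc else run - 1 / (p - m_in)
    nu[l] <- run
  }
  if (variant == "max-deviation") nu[which.max(abs(nu))]
  else max(c(nu, 0)) + min(c(nu, 0))
}

# Balanced accuracy of binary calls against logical truth.
balanced_accuracy <- function(call, truth) {
  stopifnot(any(truth), any(!truth))
  (mean(call[truth]) + mean(!call[!truth])) / 2
}

# Small labelled log2 expression matrix with reproducible values.
random_log2_matrix <- function(p, n, seed) {
  set.seed(seed)
  matrix(rnorm(p * n, 5, 2), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%02d", seq_len(n))))
}

# A 0/1 activation call matrix from explicit group counts over two
# pathways: n11 both active, n10 only p1, n01 only p2, n00 neither.
calls_from_counts <- function(n11, n10, n01, n00, p1 = "EGFR",
                              p2 = "Src", population = "tumor") {
  a1 <- c(rep(1, n11), rep(1, n10), rep(0, n01), rep(0, n00))
  a2 <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  m <- rbind(a1, a2)
  n <- length(a1)
  dimnames(m) <- list(c(p1, p2), sprintf("%s_c%03d", population, 1:n))
  m
}

# Conditions used for the planted-cohort recovery checks: one tumor
# population with both-active / p1-only / p2-only / inactive
# subpopulations over the focal pathway pair.
mixed_activation_config <- function(n_cells, seed, effect_size = 1.0,
                                    dropout_rate = 0.3) {
  simulation_config(
    seed = seed, effect_size = effect_size, dropout_rate = dropout_rate,
    n_cells_per_population = c(tumor = as.integer(n_cells)),
    subpopulation_design = list(
      list(population = "tumor", fraction = 0.25,
           active = c("EGFR", "Src")),
      list(population = "tumor", fraction = 0.30, active = "EGFR"),
      list(population = "tumor", fraction = 0.30, active = "Src"),
      list(population = "tumor", fraction = 0.15,
           active = character())))
}

# Null cohort: no planted effect and no dropout, so genes are fully
# exchangeable and the random-set cutoff faces a symmetric null.
null_cohort_config <- function(n_cells, seed) {
  simulation_config(
    seed = seed, effect_size = 0, dropout_rate = 0,
    n_cells_per_population = c(tumor = as.integer(n_cells)),
    subpopulation_design = list(
      list(population = "tumor", fraction = 1, active = character())))
}
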