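#' Gaussian-kernel CDF estimates per gene
#'
#' First stage of the per-sample gene-set variation score. For gene i with
#' values x_i1..x_in across samples, the kernel CDF at sample j is
#' `F_ij = (1/n) sum_m pnorm((x_ij - x_im) / h_i)` with per-gene bandwidth
#' `h_i = s_i / 4` (s_i = sample standard deviation across samples). A gene
#' with zero variance gets the bandwidth floor 1e-6, which leaves all its
#' F values at the neutral 0.5.
#'
#' @param x `ExpressionMatrix` on the log2 scale (or a numeric matrix,
#'   assumed log2), with at least 2 samples.
#' @return object of class `RankStatMatrix` holding `fhat` (genes x
#'   samples, values in (0,1)), `bandwidth`, and dimension metadata. Ranks
#'   are filled in by [rank_statistic()].
#' @export
kernel_cdf <- function(x) {
  m <- if (is_expression_matrix(x)) {
    if (x$scale != "log2")
      stop("kernel CDF estimation expects log2-scale expression")
    x$values
  } else x
  if (ncol(m) < 2)
    stop("kernel CDF needs at least 2 samples")
  p <- nrow(m); n <- ncol(m)
  s <- apply(m, 1, stats::sd)
  h <- pmax(s / 4, 1e-6)
  fhat <- matrix(0, p, n, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    d <- outer(m[i, ], m[i, ], "-") / h[i]
    fhat[i, ] <- rowMeans(stats::pnorm(d))
  }
  structure(list(fhat = fhat, bandwidth = h, p = p, n = n,
                 gene_ids = rownames(m), sample_ids = colnames(m),
                 rank = NULL, rstat = NULL, ord = NULL),
            class = "RankStatMatrix")
}

#' Symmetric rank statistics from kernel CDF values
#'
#' Second stage: per sample, genes are ranked by decreasing kernel CDF
#' (ties broken by ascending gene index, giving a deterministic total
#' order), and each gene receives the symmetric rank statistic
#' `r_ij = |p/2 - rank_ij|`, which up-weights both expression extremes.
#'
#' @param rsm a `RankStatMatrix` from [kernel_cdf()].
#' @return The `RankStatMatrix` with `rank` (genes x samples), `rstat`
#'   (genes x samples) and `ord` (rank-to-gene index map) filled in.
#' @export
rank_statistic <- function(rsm) {
  stopifnot(inherits(rsm, "RankStatMatrix"))
  p <- rsm$p; n <- rsm$n
  rank_m <- matrix(0L, p, n, dimnames = dimnames(rsm$fhat))
  ord_m <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    o <- order(-rsm$fhat[, j], seq_len(p))
    ord_m[, j] <- o
    rank_m[o, j] <- seq_len(p)
  }
  rsm$rank <- rank_m
  rsm$ord <- ord_m
  rsm$rstat <- abs(p / 2 - rank_m)
  rsm
}

#' @export
print.RankStatMatrix <- function(x, ...) {
  cat(sprintf("RankStatMatrix: %d genes x %d samples (%s)\n", x$p, x$n,
              if (is.null(x$rank)) "kernel CDF only"
              else "ranks computed"))
  invisible(x)
}

membership_matrix <- function(rsm, sets) {
  mem <- matrix(FALSE, rsm$p, length(sets))
  for (k in seq_along(sets)) {
    idx <- match(sets[[k]], rsm$gene_ids)
    idx <- idx[!is.na(idx)]
    mem[idx, k] <- TRUE
  }
  mem
}

walk_variant_code <- function(variant) {
  match(match.arg(variant, c("max-deviation", "diff-of-extremes")),
        c("max-deviation", "diff-of-extremes")) - 1L
}

#' Weighted random-walk enrichment score for one gene set
#'
#' Third stage: walking the genes of one sample in rank order l = 1..p, the
#' walk rises by the gene's normalized rank-statistic weight `r^tau /
#' sum(r^tau over the set)` when the gene is in the set and falls by
#' `1/(p - |set|)` otherwise, so it always returns to 0 at l = p. The
#' enrichment score is the signed maximum deviation of the walk
#' (`variant = "max-deviation"`), or the sum of its largest positive and
#' largest negative excursions (`variant = "diff-of-extremes"`).
#'
#' @param rsm a `RankStatMatrix` with ranks computed (see
#'   [rank_statistic()]).
#' @param gs a [gene_set()] (or character vector of gene IDs).
#' @param tau exponent on the rank statistic (default 1).
#' @param variant `"max-deviation"` (default) or `"diff-of-extremes"`.
#' @return named numeric vector of enrichment scores, one per sample, in
#'   [-1, 1].
#' @export
enrichment_walk <- function(rsm, gs, tau = 1,
                            variant = c("max-deviation",
                                        "diff-of-extremes")) {
  stopifnot(inherits(rsm, "RankStatMatrix"))
  if (is.null(rsm$rank)) rsm <- rank_statistic(rsm)
  members <- if (inherits(gs, "GeneSet")) gs$members else as.character(gs)
  name <- if (inherits(gs, "GeneSet")) gs$name else "gene set"
  inside <- intersect(members, rsm$gene_ids)
  if (!length(inside))
    stop("'", name, "' has no genes in the expression universe")
  if (length(inside) == rsm$p)
    stop("'", name, "' covers all genes: degenerate complement")
  mem <- membership_matrix(rsm, list(inside))
  es <- es_walk_batch(rsm$ord, rsm$rstat, mem, tau,
                      walk_variant_code(variant))
  setNames(es[1, ], rsm$sample_ids)
}

#' Score a gene-set collection across all samples
#'
#' Runs [kernel_cdf()], [rank_statistic()] and [enrichment_walk()] for
#' every set of a collection. Sets are restricted to genes present in the
#' matrix; the effective memberships are recorded in the result.
#'
#' @param x `ExpressionMatrix` on the log2 scale, or a precomputed
#'   `RankStatMatrix`.
#' @param collection a [gene_set_collection()].
#' @param tau,variant passed to [enrichment_walk()].
#' @return object of class `PathwayScoreMatrix`: list with `scores` (sets x
#'   samples), `effective_sets`, `tau`, `variant`,
#'   `reference_normalized = FALSE`.
#' @export
score_collection <- function(x, collection, tau = 1,
                             variant = c("max-deviation",
                                         "diff-of-extremes")) {
  variant <- match.arg(variant)
  rsm <- if (inherits(x, "RankStatMatrix")) x else
    rank_statistic(kernel_cdf(x))
  if (is.null(rsm$rank)) rsm <- rank_statistic(rsm)
  eff <- lapply(collection$sets,
                function(s) intersect(s$members, rsm$gene_ids))
  empty <- names(eff)[lengths(eff) == 0]
  if (length(empty))
    stop("gene set(s) with no genes in the expression universe: ",
         paste(empty, collapse = ", "))
  full <- names(eff)[lengths(eff) == rsm$p]
  if (length(full))
    stop("gene set(s) covering all genes (degenerate complement): ",
         paste(full, collapse = ", "))
  mem <- membership_matrix(rsm, eff)
  es <- es_walk_batch(rsm$ord, rsm$rstat, mem, tau,
                      walk_variant_code(variant))
  dimnames(es) <- list(names(collection), rsm$sample_ids)
  structure(list(scores = es, effective_sets = eff, tau = tau,
                 variant = variant, reference_normalized = FALSE),
            class = "PathwayScoreMatrix")
}

#' @export
print.PathwayScoreMatrix <- function(x, ...) {
  cat(sprintf(paste0("PathwayScoreMatrix: %d sets x %d samples ",
                     "(tau = %g, %s%s)\n"),
              nrow(x$scores), ncol(x$scores), x$tau, x$variant,
              if (x$reference_normalized) ", reference-normalized" else ""))
  invisible(x)
}

#' Normalize pathway scores to a reference profile
#'
#' Subtracts, per gene set, the mean enrichment score of the reference
#' samples (e.g. normal kidney tissue) from every sample's score, so the
#' reference averages 0 and tumor scores read as activation relative to
#' normal. Score differences between any two samples are preserved exactly.
#'
#' @param scores a `PathwayScoreMatrix`.
#' @param reference_sample_ids sample IDs to use as the reference; must be
#'   present and non-empty.
#' @return The normalized `PathwayScoreMatrix` (flag set).
#' @export
normalize_to_reference <- function(scores, reference_sample_ids) {
  stopifnot(inherits(scores, "PathwayScoreMatrix"))
  if (!length(reference_sample_ids))
    stop("reference sample set is empty")
  missing <- setdiff(reference_sample_ids, colnames(scores$scores))
  if (length(missing))
    stop("reference samples absent from the score matrix: ",
         paste(head(missing, 5), collapse = ", "))
  ref_mean <- rowMeans(scores$scores[, reference_sample_ids,
                                     drop = FALSE])
  scores$scores <- scores$scores - ref_mean
  scores$reference_normalized <- TRUE
  scores
}

# Stable per-set seed so activation calls for one set do not depend on
# which other sets are scored alongside it.
per_set_seed <- function(seed, set_name) substream_seed(seed, set_name)

#' Binarize pathway activation against a size-matched random-set null
#'
#' For each gene set, draws `n_random` random gene sets of the same
#' effective size (uniformly, without replacement within each draw) from
#' the expression universe, scores them in every sample, and uses the
#' per-sample mean of the random scores as the activation cutoff: a set is
#' called active in a sample iff its observed score strictly exceeds that
#' sample's cutoff. Random draws use a per-set seed derived from the master
#' seed and the set name, so calls are stable under adding or removing
#' other sets.
#'
#' @param x `ExpressionMatrix` (log2 scale) or precomputed
#'   `RankStatMatrix`.
#' @param collection a [gene_set_collection()].
#' @param n_random number of random null sets per gene set (default 1000).
#' @param seed master seed.
#' @param tau,variant passed to the enrichment walk.
#' @return object of class `ActivationCallMatrix`: list with `calls`
#'   (sets x samples, 0/1), `scores` (observed), `cutoffs` (per set and
#'   sample), `n_random`, `seed`, `tau`, `variant`.
#' @export
binarize_activation <- function(x, collection, n_random = 1000, seed = 1,
                                tau = 1,
                                variant = c("max-deviation",
                                            "diff-of-extremes")) {
  variant <- match.arg(variant)
  stopifnot(n_random > 0)
  rsm <- if (inherits(x, "RankStatMatrix")) x else
    rank_statistic(kernel_cdf(x))
  if (is.null(rsm$rank)) rsm <- rank_statistic(rsm)
  obs <- score_collection(rsm, collection, tau = tau, variant = variant)
  vcode <- walk_variant_code(variant)
  cutoffs <- matrix(NA_real_, length(collection), rsm$n,
                    dimnames = dimnames(obs$scores))
  for (k in seq_along(collection$sets)) {
    m <- length(obs$effective_sets[[k]])
    if (m >= rsm$p)
      stop("set size equals universe size for ",
           names(collection)[k])
    set.seed(per_set_seed(seed, names(collection)[k]))
    mem <- matrix(FALSE, rsm$p, n_random)
    for (b in seq_len(n_random))
      mem[sample.int(rsm$p, m), b] <- TRUE
    null_es <- es_walk_batch(rsm$ord, rsm$rstat, mem, tau, vcode)
    cutoffs[k, ] <- colMeans(null_es)
  }
  structure(list(calls = (obs$scores > cutoffs) * 1L,
                 scores = obs$scores, cutoffs = cutoffs,
                 sample_groups = if (is_expression_matrix(x)) x$groups
                                 else NULL,
                 n_random = n_random, seed = seed, tau = tau,
                 variant = variant),
            class = "ActivationCallMatrix")
}

#' @export
print.ActivationCallMatrix <- function(x, ...) {
  cat(sprintf(paste0("ActivationCallMatrix: %d sets x %d samples ",
                     "(n_random = %d, seed = %d)\n"),
              nrow(x$calls), ncol(x$calls), x$n_random, x$seed))
  cat("activation rate per set:\n")
  print(round(rowMeans(x$calls), 3))
  invisible(x)
}
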