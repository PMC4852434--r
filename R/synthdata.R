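#' Default drug-to-pathway map
#'
#' The ten-drug targeted panel used throughout: EGFR inhibitors (afatinib,
#' gefitinib, erlotinib), the Src inhibitor dasatinib, the MEK inhibitor
#' selumetinib, the c-Met inhibitor crizotinib, the mTOR inhibitor
#' temsirolimus, and the multi-target VEGFR inhibitors (pazopanib,
#' sunitinib, sorafenib).
#'
#' @return named character vector: drug label -> pathway label.
#' @export
default_drug_pathway_map <- function() {
  c(afatinib     = "EGFR",
    gefitinib    = "EGFR",
    erlotinib    = "EGFR",
    dasatinib    = "Src",
    selumetinib  = "MEK",
    crizotinib   = "c-Met",
    temsirolimus = "mTOR",
    pazopanib    = "VEGFR",
    sunitinib    = "VEGFR",
    sorafenib    = "VEGFR")
}

default_subpopulation_design <- function() {
  list(
    list(population = "parental_mRCC", fraction = 0.235,
         active = c("EGFR", "Src")),
    list(population = "parental_mRCC", fraction = 0.309, active = "EGFR"),
    list(population = "parental_mRCC", fraction = 0.309, active = "Src"),
    list(population = "parental_mRCC", fraction = 0.147,
         active = character()),
    list(population = "PDX_mRCC", fraction = 0.278,
         active = c("EGFR", "Src")),
    list(population = "PDX_mRCC", fraction = 0.2915, active = "EGFR"),
    list(population = "PDX_mRCC", fraction = 0.2915, active = "Src"),
    list(population = "PDX_mRCC", fraction = 0.139, active = character()),
    list(population = "PDX_pRCC", fraction = 0.70, active = "c-Met"),
    list(population = "PDX_pRCC", fraction = 0.30, active = character())
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated study: a renal-cell
#'-carcinoma-like design with a parental metastatic tumor and two
#' patient-derived-xenograft populations, planted subpopulation pathway
#' activation, single-cell dropout, matched bulk and normal-reference
#' profiles, and a cell-line drug-response training panel in which log10
#' IC50 depends linearly on a latent pathway activity.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param pathways pathway labels; one synthetic gene set is planted per
#'   label.
#' @param gene_set_sizes number of genes per pathway set (recycled to
#'   `length(pathways)`); sets are disjoint.
#' @param n_cells_per_population named integer vector: population label ->
#'   number of single cells.
#' @param n_normal number of normal-reference samples.
#' @param subpopulation_design list of `list(population, fraction, active)`
#'   entries; fractions within each population must sum to 1. `active` is a
#'   character vector of pathway labels switched on in that subpopulation.
#'   When `NULL`, the built-in four-group design over EGFR/Src (and c-Met
#'   for PDX_pRCC) is used for the standard population labels, and any
#'   other population gets a single no-activation subpopulation.
#' @param effect_size shift, in log2 expression units, applied to the genes
#'   of an active pathway set.
#' @param dropout_rate probability that a truly expressed gene reads 0 TPM
#'   in a single cell (Bernoulli, independent per gene and cell).
#' @param batch_offsets list with element `cell_line = list(additive,
#'   multiplicative)`: the planted batch effect separating the cell-line
#'   training panel from the study samples, applied on the log2 scale
#'   around each gene's baseline mean.
#' @param n_cell_lines number of training cell lines.
#' @param drug_map named character vector drug -> pathway; every pathway
#'   referenced must be in `pathways`.
#' @param ic50_intercept,ic50_slope,ic50_noise_sd parameters of the planted
#'   response model `log10 IC50 (nM) = intercept - slope * activity +
#'   N(0, noise_sd)`.
#' @param focal_pathways the pathway pair used for the four-group
#'   ground-truth cell labels.
#' @param seed master seed; every generator derives its substream from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              pathways = c("EGFR", "Src", "MEK", "c-Met",
                                           "mTOR", "VEGFR"),
                              gene_set_sizes = 50L,
                              n_cells_per_population = c(parental_mRCC = 34L,
                                                         PDX_mRCC = 36L,
                                                         PDX_pRCC = 46L),
                              n_normal = 10L,
                              subpopulation_design = NULL,
                              effect_size = 1.0,
                              dropout_rate = 0.3,
                              batch_offsets = list(
                                cell_line = list(additive = 1.0,
                                                 multiplicative = 1.5)),
                              n_cell_lines = 50L,
                              drug_map = default_drug_pathway_map(),
                              ic50_intercept = 2.5,
                              ic50_slope = 1.0,
                              ic50_noise_sd = 0.3,
                              focal_pathways = c("EGFR", "Src"),
                              seed = 1L) {
  gene_set_sizes <- rep_len(as.integer(gene_set_sizes), length(pathways))
  if (is.null(subpopulation_design)) {
    # default design entries for the populations actually configured;
    # any other population defaults to no planted activation
    des <- Filter(function(e)
      e$population %in% names(n_cells_per_population) &&
        all(e$active %in% pathways),
      default_subpopulation_design())
    covered <- vapply(des, `[[`, "", "population")
    for (pop in setdiff(names(n_cells_per_population), covered))
      des[[length(des) + 1L]] <- list(population = pop, fraction = 1,
                                      active = character())
    subpopulation_design <- des
  }
  cfg <- list(n_genes = as.integer(n_genes), pathways = pathways,
              gene_set_sizes = gene_set_sizes,
              n_cells_per_population = n_cells_per_population,
              n_normal = as.integer(n_normal),
              subpopulation_design = subpopulation_design,
              effect_size = effect_size, dropout_rate = dropout_rate,
              batch_offsets = batch_offsets,
              n_cell_lines = as.integer(n_cell_lines),
              drug_map = drug_map, ic50_intercept = ic50_intercept,
              ic50_slope = ic50_slope, ic50_noise_sd = ic50_noise_sd,
              focal_pathways = focal_pathways, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_normal > 0, cfg$n_cell_lines > 0)
  if (any(cfg$n_cells_per_population <= 0))
    stop("all population sizes must be positive")
  if (is.null(names(cfg$n_cells_per_population)))
    stop("`n_cells_per_population` must be named by population label")
  if (any(cfg$gene_set_sizes >= cfg$n_genes))
    stop("each gene set size must be smaller than n_genes")
  if (sum(cfg$gene_set_sizes) > cfg$n_genes)
    stop("total gene set size ", sum(cfg$gene_set_sizes),
         " exceeds n_genes = ", cfg$n_genes,
         "; disjoint sets are impossible")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  pops <- vapply(cfg$subpopulation_design, `[[`, "", "population")
  unknown_pop <- setdiff(pops, names(cfg$n_cells_per_population))
  if (length(unknown_pop))
    stop("subpopulation_design references unknown population(s): ",
         paste(unknown_pop, collapse = ", "))
  for (pop in unique(pops)) {
    fr <- vapply(cfg$subpopulation_design[pops == pop], `[[`, 0, "fraction")
    if (abs(sum(fr) - 1) > 1e-8)
      stop("subpopulation fractions for '", pop, "' sum to ", sum(fr),
           ", not 1")
  }
  active <- unique(unlist(lapply(cfg$subpopulation_design, `[[`, "active")))
  unknown <- setdiff(active, cfg$pathways)
  if (length(unknown))
    stop("subpopulation_design activates unknown pathway(s): ",
         paste(unknown, collapse = ", "))
  bad_drug <- setdiff(unname(cfg$drug_map), cfg$pathways)
  if (length(bad_drug))
    stop("drug_map targets unknown pathway(s): ",
         paste(unique(bad_drug), collapse = ", "))
  if (length(cfg$focal_pathways) != 2 ||
      !all(cfg$focal_pathways %in% cfg$pathways))
    stop("focal_pathways must name two pathways present in `pathways`")
  invisible(cfg)
}

# Deterministic substream seed: 31-adic hash of the stream name folded into
# the master seed, kept inside the 32-bit signed range.
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

baseline_log2_means <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "baseline"))
  stats::runif(cfg$n_genes, 2, 8)
}

gene_universe <- function(cfg) sprintf("g%05d", seq_len(cfg$n_genes))

#' Generate disjoint synthetic pathway gene sets
#'
#' Samples `gene_set_sizes[k]` genes per pathway, without replacement across
#' sets, from the simulated gene universe.
#'
#' @param config a [simulation_config()].
#' @return A [gene_set_collection()] with one set per configured pathway.
#' @export
generate_gene_sets <- function(config) {
  validate_simulation_config(config)
  set.seed(substream_seed(config$seed, "gene_sets"))
  universe <- gene_universe(config)
  picked <- sample(universe, sum(config$gene_set_sizes))
  idx <- 0L
  sets <- vector("list", length(config$pathways))
  for (k in seq_along(config$pathways)) {
    m <- config$gene_set_sizes[k]
    sets[[k]] <- gene_set(config$pathways[k],
                          picked[(idx + 1L):(idx + m)],
                          description = "synthetic pathway set")
    idx <- idx + m
  }
  gene_set_collection(sets, source = "sccombo synthetic generator")
}

# Largest-remainder apportionment of n cells over subpopulation fractions;
# deterministic, ties resolved in design order.
apportion <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

group_label <- function(a1, a2, p1, p2) {
  ifelse(a1 & a2, "both-active",
         ifelse(a1, paste0(p1, "-only"),
                ifelse(a2, paste0(p2, "-only"), "both-inactive")))
}

#' Generate a synthetic single-cell cohort with matched bulks and normals
#'
#' Per-gene baseline log2 abundance is Uniform(2, 8) with unit-variance
#' Gaussian cell-to-cell noise; genes in a pathway set that is active in a
#' cell's subpopulation are shifted by `effect_size` log2 units; values are
#' exponentiated to linear TPM and zeroed by Bernoulli dropout. Each
#' population's bulk profile is the linear-scale mean of its (post-dropout)
#' cells times 1% multiplicative noise; normal references are baseline draws
#' with no activation and no dropout.
#'
#' Substream order (all derived from the master seed, so each output is
#' reproducible in isolation): baseline means, gene sets, cells, dropout,
#' bulk noise, normals.
#'
#' @param config a [simulation_config()].
#' @param collection optionally a pre-built [gene_set_collection()]; by
#'   default [generate_gene_sets()] output.
#' @return list with `cells`, `bulks`, `normals` (each an
#'   `ExpressionMatrix` on linear TPM scale), `collection`, and `truth`:
#'   per-cell logical activation flags (pathway x cell), the four-group
#'   label over `focal_pathways`, and per-sample batch assignments.
#' @export
generate_expression_cohort <- function(config, collection = NULL) {
  validate_simulation_config(config)
  if (is.null(collection)) collection <- generate_gene_sets(config)
  universe <- gene_universe(config)
  bad <- setdiff(unique(unlist(lapply(config$subpopulation_design,
                                      `[[`, "active"))),
                 names(collection))
  if (length(bad))
    stop("subpopulation design activates pathway(s) absent from the gene ",
         "set collection: ", paste(bad, collapse = ", "))
  mu <- baseline_log2_means(config)
  set_rows <- lapply(collection$sets,
                     function(s) match(s$members, universe))

  pops <- names(config$n_cells_per_population)
  design_pop <- vapply(config$subpopulation_design, `[[`, "", "population")

  set.seed(substream_seed(config$seed, "cells"))
  cell_cols <- list(); flags <- list(); cell_pop <- character()
  for (pop in pops) {
    entries <- config$subpopulation_design[design_pop == pop]
    if (!length(entries))
      entries <- list(list(population = pop, fraction = 1,
                           active = character()))
    counts <- apportion(vapply(entries, `[[`, 0, "fraction"),
                        config$n_cells_per_population[[pop]])
    for (e in seq_along(entries)) {
      active <- entries[[e]]$active
      for (i in seq_len(counts[e])) {
        x <- mu + stats::rnorm(config$n_genes)
        for (p in active) x[set_rows[[p]]] <- x[set_rows[[p]]] +
            config$effect_size
        cell_cols[[length(cell_cols) + 1L]] <- 2^x
        flags[[length(flags) + 1L]] <- names(collection) %in% active
        cell_pop <- c(cell_pop, pop)
      }
    }
  }
  cells <- do.call(cbind, cell_cols)
  flag_mat <- do.call(cbind, flags)
  cell_ids <- unlist(lapply(pops, function(pop)
    sprintf("%s_c%03d", pop, seq_len(sum(cell_pop == pop)))))
  dimnames(cells) <- list(universe, cell_ids)
  dimnames(flag_mat) <- list(names(collection), cell_ids)

  set.seed(substream_seed(config$seed, "dropout"))
  if (config$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(cells)) < config$dropout_rate,
                   nrow(cells))
    cells[drop] <- 0
  }

  set.seed(substream_seed(config$seed, "bulk"))
  bulks <- vapply(pops, function(pop) {
    rowMeans(cells[, cell_pop == pop, drop = FALSE]) *
      (1 + stats::rnorm(config$n_genes, 0, 0.01))
  }, numeric(config$n_genes))
  bulks <- pmax(bulks, 0)
  colnames(bulks) <- paste0("bulk_", pops)

  set.seed(substream_seed(config$seed, "normals"))
  normals <- vapply(seq_len(config$n_normal),
                    function(i) 2^(mu + stats::rnorm(config$n_genes)),
                    numeric(config$n_genes))
  dimnames(normals) <- list(universe,
                            sprintf("normal_%02d", seq_len(config$n_normal)))

  fp <- config$focal_pathways
  truth <- list(
    activation = flag_mat,
    group = setNames(group_label(flag_mat[fp[1], ], flag_mat[fp[2], ],
                                 fp[1], fp[2]), cell_ids),
    batch = setNames(rep("study", length(cell_ids) + length(pops) +
                           config$n_normal),
                     c(cell_ids, colnames(bulks), colnames(normals))),
    focal_pathways = fp)

  list(cells = expression_matrix(cells,
                                 groups = setNames(cell_pop, cell_ids)),
       bulks = expression_matrix(bulks,
                                 groups = setNames(pops, colnames(bulks))),
       normals = expression_matrix(
         normals, groups = setNames(rep("normal", config$n_normal),
                                    colnames(normals))),
       collection = collection,
       truth = truth)
}

#' Generate a synthetic cell-line drug-response training panel
#'
#' Each cell line carries a latent standard-normal activity per pathway; the
#' pathway's genes are shifted by `effect_size * activity` log2 units, and
#' each drug's response follows `log10 IC50 (nM) = ic50_intercept -
#' ic50_slope * activity(target pathway) + N(0, ic50_noise_sd)`. The
#' configured cell-line batch effect (additive shift plus multiplicative
#' inflation of deviations around the gene baseline, on the log2 scale) is
#' applied to the cell-line matrix only, so the training panel and the study
#' samples form distinct batches.
#'
#' @param config a [simulation_config()].
#' @param collection a [gene_set_collection()] covering every pathway in
#'   `config$drug_map` (default: [generate_gene_sets()]).
#' @return list with `expr` (cell-line `ExpressionMatrix`, linear TPM),
#'   `response` (data frame, rows = cell lines, columns = drugs, log10 nM),
#'   and `truth` (latent activity matrix, noiseless response component, and
#'   the planted batch parameters).
#' @export
generate_drug_training_set <- function(config, collection = NULL) {
  validate_simulation_config(config)
  if (is.null(collection)) collection <- generate_gene_sets(config)
  bad <- setdiff(unname(config$drug_map), names(collection))
  if (length(bad))
    stop("drug_map targets pathway(s) absent from the collection: ",
         paste(unique(bad), collapse = ", "))
  universe <- gene_universe(config)
  mu <- baseline_log2_means(config)
  set_rows <- lapply(collection$sets, function(s) match(s$members, universe))

  set.seed(substream_seed(config$seed, "cell_lines"))
  nl <- config$n_cell_lines
  line_ids <- sprintf("line_%03d", seq_len(nl))
  activity <- matrix(stats::rnorm(length(config$pathways) * nl),
                     length(config$pathways), nl,
                     dimnames = list(config$pathways, line_ids))
  X <- mu + matrix(stats::rnorm(config$n_genes * nl), config$n_genes, nl)
  for (p in config$pathways)
    X[set_rows[[p]], ] <- X[set_rows[[p]], ] +
      config$effect_size * rep(activity[p, ], each = length(set_rows[[p]]))

  off <- config$batch_offsets$cell_line
  if (!is.null(off))
    X <- mu + off$multiplicative * (X - mu) + off$additive

  drugs <- names(config$drug_map)
  signal <- t(vapply(drugs, function(d)
    config$ic50_intercept -
      config$ic50_slope * activity[config$drug_map[[d]], ],
    numeric(nl)))
  y <- signal + matrix(stats::rnorm(length(signal), 0, config$ic50_noise_sd),
                       nrow(signal))
  dimnames(y) <- dimnames(signal) <- list(drugs, line_ids)

  expr <- pmax(2^X, 0)
  dimnames(expr) <- list(universe, line_ids)
  list(expr = expression_matrix(expr,
                                groups = setNames(rep("cell_line", nl),
                                                  line_ids)),
       response = as.data.frame(t(y)),
       truth = list(activity = activity, response_signal = signal,
                    response = y,
                    batch = setNames(rep("cell_line", nl), line_ids),
                    batch_offsets = off))
}

#' Generate a per-cell QC metrics table with controlled pass counts
#'
#' Emits one row per captured cell with sequencing-depth and mapping
#' metrics. Exactly `pass_counts[pop]` cells per population satisfy all four
#' QC thresholds strictly (reads > 1e6, uniquely-mapped rate > 0.60, exonic
#' rate > 0.35, detected genes > 5000); every other cell fails at least one
#' criterion, including cells placed exactly on a threshold boundary (which
#' must fail, the thresholds being strict).
#'
#' @param config a [simulation_config()].
#' @param pass_counts named integer vector population -> number of passing
#'   cells; defaults to all cells passing.
#' @return data frame with columns `sample_id`, `reads`,
#'   `unique_map_rate`, `exonic_rate`, `detected_genes`, `population`.
#' @export
generate_qc_table <- function(config,
                              pass_counts = config$n_cells_per_population) {
  validate_simulation_config(config)
  pops <- names(config$n_cells_per_population)
  if (is.null(names(pass_counts))) names(pass_counts) <- pops
  bad <- setdiff(names(pass_counts), pops)
  if (length(bad))
    stop("pass_counts for unknown population(s): ",
         paste(bad, collapse = ", "))
  set.seed(substream_seed(config$seed, "qc"))
  rows <- list()
  # Failure modes cycled over failing cells; the first four sit exactly on a
  # threshold boundary to pin down the strict inequality.
  fail_modes <- list(
    function(r) { r$reads <- 1e6; r },
    function(r) { r$unique_map_rate <- 0.60; r },
    function(r) { r$exonic_rate <- 0.35; r },
    function(r) { r$detected_genes <- 5000L; r },
    function(r) { r$reads <- stats::runif(1, 1e5, 9e5); r },
    function(r) { r$unique_map_rate <- stats::runif(1, 0.1, 0.55)
                  r$detected_genes <- sample(500:4500, 1); r })
  for (pop in pops) {
    n <- config$n_cells_per_population[[pop]]
    npass <- as.integer(pass_counts[[pop]])
    if (is.na(npass) || npass < 0 || npass > n)
      stop("pass_counts['", pop, "'] must be between 0 and ", n)
    pass_idx <- sort(sample(n, npass))
    mode_i <- 0L
    for (i in seq_len(n)) {
      rec <- list(sample_id = sprintf("%s_c%03d", pop, i),
                  reads = stats::runif(1, 1.2e6, 4e6),
                  unique_map_rate = stats::runif(1, 0.65, 0.95),
                  exonic_rate = stats::runif(1, 0.40, 0.70),
                  detected_genes = sample(5500:9000, 1),
                  population = pop)
      if (!(i %in% pass_idx)) {
        mode_i <- mode_i %% length(fail_modes) + 1L
        rec <- fail_modes[[mode_i]](rec)
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}
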