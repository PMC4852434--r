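#' Default analysis constants
#'
#' The numeric thresholds used across the pipeline: QC cut-offs (reads,
#' uniquely-mapped rate, exonic rate, detected genes), the TPM detection
#' rule, permutation counts, the variance-filter fraction, the
#' differential-expression cut-offs, and `combo_populations` (population
#' labels the combination is selected over; `NULL` pools all QC-passing
#' cells).
#'
#' @return named list of defaults.
#' @export
analysis_defaults <- function() {
  list(min_reads = 1e6,
       min_unique_map_rate = 0.60,
       min_exonic_rate = 0.35,
       min_detected_genes = 5000,
       tpm_threshold = 1,
       group_fraction = 0.10,
       n_random = 1000,
       n_permutations = 1000,
       drop_fraction = 0.20,
       fdr_cutoff = 0.01,
       fc_cutoff = 2,
       tau = 1,
       variant = "max-deviation",
       lambda = "auto",
       batch_mode = "eb",
       combo_populations = NULL)
}

#' Build a full pipeline configuration
#'
#' Bundles the simulation design, every stage parameter (all defaulting
#' to [analysis_defaults()]), the focal pathway pair, and the master seed.
#' Round-trips losslessly through YAML.
#'
#' @param simulation a [simulation_config()] (its seed is kept in sync
#'   with `seed`).
#' @param seed master seed; stage seeds are derived by stable hashing of
#'   (seed, stage name).
#' @param ... overrides for any [analysis_defaults()] entry.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulation = simulation_config(seed = seed),
                            seed = 1L, ...) {
  params <- analysis_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) params[nm] <- list(dots[[nm]])
  structure(list(simulation = simulation, params = params,
                 focal_pathways = simulation$focal_pathways,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- list(seed = config$seed,
              params = config$params,
              focal_pathways = config$focal_pathways,
              simulation = unclass(config$simulation))
  obj$simulation$drug_map <- as.list(config$simulation$drug_map)
  obj$simulation$n_cells_per_population <-
    as.list(config$simulation$n_cells_per_population)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim <- obj$simulation
  cfg <- simulation_config(
    n_genes = sim$n_genes, pathways = sim$pathways,
    gene_set_sizes = sim$gene_set_sizes,
    n_cells_per_population = unlist(sim$n_cells_per_population),
    n_normal = sim$n_normal,
    subpopulation_design = lapply(sim$subpopulation_design, function(e)
      list(population = e$population, fraction = e$fraction,
           active = as.character(unlist(e$active)))),
    effect_size = sim$effect_size, dropout_rate = sim$dropout_rate,
    batch_offsets = sim$batch_offsets,
    n_cell_lines = sim$n_cell_lines, drug_map = unlist(sim$drug_map),
    ic50_intercept = sim$ic50_intercept, ic50_slope = sim$ic50_slope,
    ic50_noise_sd = sim$ic50_noise_sd,
    focal_pathways = sim$focal_pathways, seed = sim$seed)
  do.call(pipeline_config,
          c(list(simulation = cfg, seed = obj$seed), obj$params))
}

#' Validate pipeline input files
#'
#' Checks expression TSVs (rectangularity, unique IDs, finite non-negative
#' TPM), GMT syntax, and QC table columns without mutating anything.
#'
#' @param paths named list/vector of file paths; recognized names are
#'   `expression` (one or more TSVs), `gmt`, `qc`.
#' @return data frame of problems (zero rows when everything validates),
#'   with columns `file`, `problem`.
#' @export
validate_inputs <- function(paths) {
  problems <- list()
  note <- function(file, problem)
    problems[[length(problems) + 1L]] <<- data.frame(file = file,
                                                     problem = problem)
  for (f in unlist(paths[names(paths) %in% c("expression", "")])) {
    if (!file.exists(f)) { note(f, "file not found"); next }
    df <- tryCatch(read.delim(f, check.names = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) { note(f, "not a readable TSV"); next }
    if (!ncol(df) || names(df)[1] != "gene_id") {
      note(f, "first column must be 'gene_id'"); next
    }
    if (anyDuplicated(df$gene_id))
      note(f, "duplicated gene IDs")
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals) || any(!is.finite(vals)))
      note(f, "non-numeric or non-finite expression values")
    else if (any(vals < 0))
      note(f, "negative TPM values")
  }
  if (!is.null(paths$gmt)) {
    f <- paths$gmt
    if (!file.exists(f)) note(f, "file not found")
    else tryCatch(invisible(read_gmt(f)),
                  error = function(e) note(f, conditionMessage(e)),
                  warning = function(w) note(f, conditionMessage(w)))
  }
  if (!is.null(paths$qc)) {
    f <- paths$qc
    if (!file.exists(f)) note(f, "file not found")
    else tryCatch(invisible(read_qc_tsv(f)),
                  error = function(e) note(f, conditionMessage(e)))
  }
  if (!length(problems))
    data.frame(file = character(), problem = character())
  else do.call(rbind, problems)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in fixed order: simulate inputs, QC-filter cells,
#' detection-filter genes, log-transform and mean-centroid normalize,
#' score pathway gene sets per sample, normalize scores to the normal
#' reference, binarize activation against the random-set null, train and
#' cross-validate per-drug ridge models on the cell-line panel (after
#' batch adjustment and variance filtering), predict and Z-score the
#' single cells, classify cells over the focal pathway pair, and select
#' the covering drug pair. Stage outputs are written as TSV/JSON under
#' `outdir` together with a manifest carrying the configuration, seeds
#' and file hashes; rerunning with the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return list with the in-memory stage results (`cohort`, `qc`,
#'   `scores`, `calls`, `models`, `loocv`, `predictions`,
#'   `classification`, `plan`, `manifest`), invisibly also written to
#'   `outdir`.
#' @export
run_pipeline <- function(config, outdir = tempfile("sccombo_run_")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  par <- config$params
  sim <- config$simulation
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cohort <- stage("simulate", generate_expression_cohort(sim))
  training <- stage("simulate-training",
                    generate_drug_training_set(sim, cohort$collection))
  qc_table <- generate_qc_table(sim)
  write_expression_tsv(cohort$cells, file.path(outdir, "cells_tpm.tsv.gz"))
  write_expression_tsv(cohort$normals,
                       file.path(outdir, "normals_tpm.tsv.gz"))
  write_gmt(cohort$collection, file.path(outdir, "gene_sets.gmt"))
  write_qc_tsv(qc_table, file.path(outdir, "qc_table.tsv"))

  qc <- stage("qc", filter_cells(qc_table,
                                 min_reads = par$min_reads,
                                 min_unique_map_rate =
                                   par$min_unique_map_rate,
                                 min_exonic_rate = par$min_exonic_rate,
                                 min_detected_genes =
                                   par$min_detected_genes))
  keep <- intersect(colnames(cohort$cells$values), qc$passing)
  cells <- expression_matrix(cohort$cells$values[, keep, drop = FALSE],
                             groups = cohort$cells$groups[keep])

  filtered <- stage("filter-genes",
                    filter_genes_by_detection(cells,
                                              par$tpm_threshold,
                                              par$group_fraction))
  genes <- rownames(filtered$values)
  normals <- expression_matrix(
    cohort$normals$values[genes, , drop = FALSE],
    groups = cohort$normals$groups)
  tumor_normal <- expression_matrix(
    cbind(filtered$values, normals$values),
    groups = c(filtered$groups, normals$groups))
  logged <- mean_centroid_normalize(log_transform(tumor_normal))

  scores <- stage("gsva", score_collection(logged, cohort$collection,
                                           tau = par$tau,
                                           variant = par$variant))
  scores_norm <- normalize_to_reference(scores,
                                        colnames(normals$values))
  calls <- stage("binarize",
                 binarize_activation(logged, cohort$collection,
                                     n_random = par$n_random,
                                     seed = substream_seed(config$seed,
                                                           "binarize"),
                                     tau = par$tau,
                                     variant = par$variant))
  calls$sample_groups <- tumor_normal$groups
  tumor_calls <- calls
  tumor_cols <- colnames(filtered$values)
  tumor_calls$calls <- calls$calls[, tumor_cols, drop = FALSE]
  tumor_calls$scores <- calls$scores[, tumor_cols, drop = FALSE]
  tumor_calls$cutoffs <- calls$cutoffs[, tumor_cols, drop = FALSE]
  tumor_calls$sample_groups <- tumor_normal$groups[tumor_cols]
  write.table(data.frame(gene_set = rownames(calls$calls), calls$calls,
                         check.names = FALSE),
              file.path(outdir, "activation_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  adj <- stage("batch-adjust",
               batch_adjust(log_transform(training$expr),
                            log_transform(cells),
                            mode = par$batch_mode))
  adj_filtered <- variance_filter(adj$adjusted, par$drop_fraction)
  train_cols <- names(adj$batch)[adj$batch == "train"]
  test_cols <- names(adj$batch)[adj$batch == "test"]
  train_m <- adj_filtered$values[, train_cols, drop = FALSE]
  test_m <- adj_filtered$values[, test_cols, drop = FALSE]

  drugs <- colnames(training$response)
  models <- stage("train", lapply(setNames(drugs, drugs), function(d)
    fit_ridge(train_m, training$response[[d]], lambda = par$lambda)))
  loocv <- stage("loocv", lapply(setNames(drugs, drugs), function(d)
    loocv_evaluate(train_m, training$response[[d]],
                   lambda = models[[d]]$lambda)))
  predictions <- stage("predict", predict_and_zscore(models, test_m))
  predictions$groups <- cells$groups[test_cols]
  write.table(data.frame(drug = rownames(predictions$z), predictions$z,
                         check.names = FALSE),
              file.path(outdir, "predicted_z.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  fp <- config$focal_pathways
  classification <- stage("classify",
                          classify_cells(tumor_calls, fp[1], fp[2],
                                         populations = cells$groups))
  # the combination question is population-scoped: restrict to the
  # populations of interest when configured (e.g. the metastatic tumor
  # and its xenograft), otherwise pool all QC-passing cells
  combo_calls <- tumor_calls
  if (!is.null(par$combo_populations)) {
    keep_cells <- names(cells$groups)[cells$groups %in%
                                        par$combo_populations]
    if (!length(keep_cells))
      stop("combo_populations selects no cells")
    combo_calls$calls <- tumor_calls$calls[, keep_cells, drop = FALSE]
  }
  plan <- stage("combo",
                select_combination(combo_calls,
                                   drug_pathway_map = sim$drug_map))

  summary <- list(
    n_cells_passing_qc = length(qc$passing),
    n_genes_after_detection_filter = nrow(filtered$values),
    percent_by_group = classification$percent,
    loocv_r = vapply(loocv, `[[`, 0, "r"),
    selected_pair = plan$selected,
    coverage = plan$table$coverage[1],
    redundancy = plan$table$redundancy[1])
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(seed = config$seed,
                   params = par,
                   config_hash = config_hash(config),
                   files = as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, training = training, qc = qc,
                 filtered = filtered, scores = scores,
                 scores_normalized = scores_norm, calls = tumor_calls,
                 models = models, loocv = loocv,
                 predictions = predictions,
                 classification = classification, plan = plan,
                 manifest = manifest, outdir = outdir))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}
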