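#' Classify cells into four groups over a pathway pair
#'
#' Each cell is assigned to one of `both-active`, `<p1>-only`,
#' `<p2>-only`, `both-inactive` according to its binary activation calls
#' for the two pathways, and per-population counts and percentages
#' (1 decimal, round-half-even) are tabulated.
#'
#' @param calls an `ActivationCallMatrix` (from [binarize_activation()])
#'   or a 0/1 matrix with pathways in rows and cells in columns.
#' @param p1,p2 the two pathway labels (distinct, present in `calls`).
#' @param populations named vector cell -> population label; defaults to
#'   the sample groups carried by `calls`, else one pooled population.
#' @return object of class `CellGroupAssignment`: list with `cell_groups`
#'   (named character vector), `counts` and `percent` (population x group
#'   tables), `percent_single_active` (the combined mutually-exclusive
#'   compartment, rounded once per population), `pathways = c(p1, p2)`.
#' @export
classify_cells <- function(calls, p1, p2, populations = NULL) {
  m <- if (inherits(calls, "ActivationCallMatrix")) calls$calls else calls
  if (is.null(populations) && inherits(calls, "ActivationCallMatrix"))
    populations <- calls$sample_groups
  if (p1 == p2) stop("p1 and p2 must be distinct pathways")
  missing <- setdiff(c(p1, p2), rownames(m))
  if (length(missing))
    stop("pathway(s) absent from the call matrix: ",
         paste(missing, collapse = ", "))
  cells <- colnames(m)
  if (is.null(populations))
    populations <- setNames(rep("all", length(cells)), cells)
  pops <- populations[cells]
  groups <- group_label(m[p1, ] == 1, m[p2, ] == 1, p1, p2)
  names(groups) <- cells
  levels <- c("both-active", paste0(p1, "-only"), paste0(p2, "-only"),
              "both-inactive")
  counts <- table(population = pops,
                  group = factor(groups, levels = levels))
  percent <- round(100 * prop.table(counts, margin = 1), 1)
  # the mutually-exclusive compartment is reported as one rounded figure
  # (rounding the two single-active percentages separately need not add
  # up to the rounded combined fraction)
  single <- round(100 * (counts[, levels[2]] + counts[, levels[3]]) /
                    rowSums(counts), 1)
  structure(list(cell_groups = groups, counts = unclass(counts),
                 percent = unclass(percent),
                 percent_single_active = single,
                 pathways = c(p1, p2), group_levels = levels),
            class = "CellGroupAssignment")
}

#' @export
print.CellGroupAssignment <- function(x, ...) {
  cat(sprintf("CellGroupAssignment over (%s, %s): %d cells\n",
              x$pathways[1], x$pathways[2], length(x$cell_groups)))
  cat("percent per population:\n")
  print(x$percent)
  invisible(x)
}

#' Compare group composition between two cell populations
#'
#' For each of the four groups, reports the fraction difference between
#' two classifications and a two-proportion test: chi-square with
#' continuity correction, falling back to Fisher's exact test when any
#' expected count is below 5.
#'
#' @param assign_a,assign_b `CellGroupAssignment` objects over the same
#'   pathway pair; each must be a single population (or have its counts
#'   pooled first).
#' @return data frame per group: `group`, `frac_a`, `frac_b`,
#'   `diff_percent` (percentage points), `p_value`, `test`.
#' @export
compare_populations <- function(assign_a, assign_b) {
  if (!identical(assign_a$pathways, assign_b$pathways))
    stop("classifications use different pathway pairs")
  ca <- colSums(assign_a$counts); cb <- colSums(assign_b$counts)
  na <- sum(ca); nb <- sum(cb)
  if (na == 0 || nb == 0) stop("empty population")
  out <- lapply(assign_a$group_levels, function(g) {
    tab <- rbind(c(ca[[g]], na - ca[[g]]), c(cb[[g]], nb - cb[[g]]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = TRUE)$p.value
      test <- "chisq"
    }
    data.frame(group = g, frac_a = ca[[g]] / na, frac_b = cb[[g]] / nb,
               # difference of the reported (1-decimal) percentages
               diff_percent = round(100 * cb[[g]] / nb, 1) -
                 round(100 * ca[[g]] / na, 1),
               p_value = p, test = test)
  })
  do.call(rbind, out)
}

#' Select the drug pair maximizing cell coverage without redundancy
#'
#' Enumerates all unordered pairs of candidate pathways that map to at
#' least one drug. For each pair, coverage is the fraction of cells with
#' at least one of the two pathways called active and redundancy the
#' fraction with both active. The selected pair maximizes coverage; ties
#' are broken by lower redundancy, then lexicographically by pair name.
#' Cells with undefined calls for either pathway are excluded from the
#' denominators and counted in the result.
#'
#' @param calls `ActivationCallMatrix` or 0/1 pathway x cell matrix.
#' @param drug_pathway_map named character vector drug -> pathway (default
#'   [default_drug_pathway_map()]).
#' @param candidate_pathways pathways to consider (default: all rows of
#'   `calls`).
#' @return object of class `CombinationPlan`: list with `table` (per-pair
#'   coverage/redundancy/drugs), `selected` (pathway pair), `drugs`
#'   (representative drug per selected pathway), `n_cells`,
#'   `n_excluded`, and `tie_break` trace.
#' @export
select_combination <- function(calls,
                               drug_pathway_map =
                                 default_drug_pathway_map(),
                               candidate_pathways = NULL) {
  m <- if (inherits(calls, "ActivationCallMatrix")) calls$calls else calls
  if (is.null(candidate_pathways)) candidate_pathways <- rownames(m)
  missing <- setdiff(candidate_pathways, rownames(m))
  if (length(missing))
    stop("candidate pathway(s) absent from the call matrix: ",
         paste(missing, collapse = ", "))
  mapped <- candidate_pathways %in% unname(drug_pathway_map)
  if (any(!mapped))
    warning("pathway(s) without a mapped drug excluded: ",
            paste(candidate_pathways[!mapped], collapse = ", "))
  eligible <- candidate_pathways[mapped]
  if (length(eligible) < 2)
    stop("fewer than 2 candidate pathways with mapped drugs")
  pairs <- utils::combn(sort(eligible), 2)
  drugs_for <- function(p)
    paste(names(drug_pathway_map)[drug_pathway_map == p], collapse = "/")
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    p <- pairs[, i]
    a <- m[p[1], ]; b <- m[p[2], ]
    ok <- !is.na(a) & !is.na(b)
    data.frame(pathway_1 = p[1], pathway_2 = p[2],
               drugs_1 = drugs_for(p[1]), drugs_2 = drugs_for(p[2]),
               coverage = mean(a[ok] == 1 | b[ok] == 1),
               redundancy = mean(a[ok] == 1 & b[ok] == 1),
               n_cells = sum(ok))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$coverage, tab$redundancy,
               paste(tab$pathway_1, tab$pathway_2))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  sel <- tab[1, ]
  tie <- sum(tab$coverage == sel$coverage)
  structure(list(
    table = tab,
    selected = c(sel$pathway_1, sel$pathway_2),
    drugs = c(sel$drugs_1, sel$drugs_2),
    n_cells = sel$n_cells,
    n_excluded = ncol(m) - sel$n_cells,
    tie_break = if (tie > 1)
      sprintf("%d pairs tied on coverage %.3f; broke by redundancy then name",
              tie, sel$coverage) else "none"),
    class = "CombinationPlan")
}

#' @export
print.CombinationPlan <- function(x, ...) {
  cat(sprintf(paste0("CombinationPlan: %s + %s (drugs %s + %s); coverage ",
                     "%.1f%%, redundancy %.1f%% over %d cells\n"),
              x$selected[1], x$selected[2], x$drugs[1], x$drugs[2],
              100 * x$table$coverage[1], 100 * x$table$redundancy[1],
              x$n_cells))
  invisible(x)
}
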