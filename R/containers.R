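#' Construct an expression matrix container
#'
#' Wraps a numeric gene-by-sample matrix together with the per-sample
#' population labels and a scale flag. All downstream stages operate on this
#' container: abundances are transcripts-per-million (TPM) on the linear
#' scale, or `log2(TPM + 1)` after [log_transform()].
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param groups optional named character vector mapping sample ID to a
#'   population label. Names must cover all samples when supplied.
#' @param scale `"tpm"` (linear) or `"log2"` (`log2(TPM + 1)`).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `groups`, `scale`.
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' x <- expression_matrix(m, groups = setNames(rep("tumor", 5), colnames(m)))
#' x
#' @export
expression_matrix <- function(values, groups = NULL,
                              scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale == "tpm" && any(values < 0))
    stop("TPM values must be non-negative")
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      stop("`groups` must be a named vector (sample ID -> population)")
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("samples without a group label: ",
           paste(head(missing, 5), collapse = ", "))
    groups <- groups[colnames(values)]
  }
  structure(list(values = values, groups = groups, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values),
              if (x$scale == "tpm") "linear TPM" else "log2(TPM+1)"))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

# Coerce a plain matrix for internal use; keeps the public surface forgiving.
as_em <- function(x, scale = "tpm") {
  if (is_expression_matrix(x)) x else expression_matrix(x, scale = scale)
}

#' Construct a gene set
#'
#' @param name set label (e.g. a pathway name).
#' @param members character vector of gene IDs; duplicates are removed.
#' @param description free-text provenance string.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!nzchar(name)) stop("gene set name must be non-empty")
  members <- unique(as.character(members))
  if (!length(members)) stop("gene set '", name, "' has no members")
  structure(list(name = name, description = description, members = members),
            class = "GeneSet")
}

#' Construct a gene set collection
#'
#' @param sets list of [gene_set()] objects (or a named list of character
#'   vectors, which is coerced).
#' @param source free-text provenance for the collection.
#' @return An object of class `GeneSetCollection`: ordered list of sets with
#'   unique names.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (!is.null(names(sets)) && !all(vapply(sets, inherits, TRUE, "GeneSet")))
    sets <- Map(gene_set, names(sets), sets)
  if (!all(vapply(sets, inherits, TRUE, "GeneSet")))
    stop("`sets` must be GeneSet objects or a named list of gene ID vectors")
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate gene set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  structure(list(sets = sets, source = source), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets\n", length(x$sets)))
  for (s in x$sets)
    cat(sprintf("  %s (%d genes)\n", s$name, length(s$members)))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
names.GeneSetCollection <- function(x) names(x$sets)

set_sizes <- function(collection)
  vapply(collection$sets, function(s) length(s$members), 0L)
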