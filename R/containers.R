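#' Methylation and expression matrix containers
#'
#' The pipeline passes around four light list-based containers in the style of
#' limma's `MAList`: a `beta_matrix` (raw beta-values in \[0,1\]), a
#' `ternary_matrix` (values stratified to 0 / 0.5 / 1), a `relative_matrix`
#' (ternary values mean-centred across tumours) and an `expression_matrix`
#' (probe-level relative expression). Each holds a numeric `values` matrix
#' (features x samples) and a `gene` map from feature id to gene symbol.
#'
#' @param values numeric matrix, rows = features (CpG sites or probes) with
#'   unique rownames, columns = samples with unique colnames.
#' @param gene character vector of gene symbols, one per row of `values`;
#'   either named by feature id or in row order.
#' @return An object of the requested class: a list with elements `values`
#'   and `gene` (named by feature id).
#' @name containers
NULL

new_meth_matrix <- function(values, gene, class, range = NULL,
                            value_set = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row and column names", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L], call. = FALSE)
  if (length(gene) != nrow(values))
    stop("'gene' must have one symbol per row of 'values'", call. = FALSE)
  if (is.null(names(gene))) names(gene) <- rownames(values)
  gene <- gene[rownames(values)]
  if (anyNA(names(gene)))
    stop("'gene' names must cover every feature id", call. = FALSE)
  v <- values[!is.na(values)]
  if (!is.null(range) && length(v) && (min(v) < range[1] || max(v) > range[2]))
    stop("values outside [", range[1], ", ", range[2], "]", call. = FALSE)
  if (!is.null(value_set) && length(v) && !all(v %in% value_set))
    stop("values outside the set {", paste(value_set, collapse = ", "), "}",
         call. = FALSE)
  structure(list(values = values, gene = gene), class = class)
}

#' @rdname containers
#' @export
beta_matrix <- function(values, gene) {
  new_meth_matrix(values, gene, "beta_matrix", range = c(0, 1))
}

#' @rdname containers
#' @export
ternary_matrix <- function(values, gene) {
  new_meth_matrix(values, gene, "ternary_matrix", value_set = c(0, 0.5, 1))
}

#' @rdname containers
#' @export
relative_matrix <- function(values, gene) {
  new_meth_matrix(values, gene, "relative_matrix", range = c(-1, 1))
}

#' @rdname containers
#' @export
expression_matrix <- function(values, gene) {
  new_meth_matrix(values, gene, "expression_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) print_meth_matrix(x, "beta-value")
#' @export
print.ternary_matrix <- function(x, ...) print_meth_matrix(x, "ternary")
#' @export
print.relative_matrix <- function(x, ...)
  print_meth_matrix(x, "relative methylation")
#' @export
print.expression_matrix <- function(x, ...)
  print_meth_matrix(x, "relative expression")

print_meth_matrix <- function(x, what) {
  cat(sprintf("%s matrix: %d features x %d samples (%d genes)\n",
              what, nrow(x$values), ncol(x$values),
              length(unique(x$gene))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)
#' @export
dim.ternary_matrix <- function(x) dim(x$values)
#' @export
dim.relative_matrix <- function(x) dim(x$values)
#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Restrict a matrix container to a set of samples
#'
#' Analyses on nested sample subsets (all tumours, expression-classified
#' tumours, ...) share one matrix; this keeps the gene map in step while
#' selecting columns.
#'
#' @param x any of the matrix containers.
#' @param samples character vector of sample ids to keep, in the given order.
#' @return The container restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  missing_ids <- setdiff(samples, colnames(x$values))
  if (length(missing_ids))
    stop("unknown sample id: ", missing_ids[1L], call. = FALSE)
  subset_meth_matrix(x, samples = samples)
}

# subset a container to given features/samples, keeping the gene map in step
subset_meth_matrix <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  x$values <- v
  x$gene <- x$gene[rownames(v)]
  x
}

# canonical gene-symbol form used for all cross-platform matching
norm_symbol <- function(x) toupper(trimws(x))

# closed subtype vocabulary; case-insensitive normalisation on read
SUBTYPE_LEVELS <- c("basal-like", "lumA", "lumB", "HER2-enriched",
                    "normal-like", "non-classified", "non-GEX")

normalise_subtype <- function(x) {
  idx <- match(tolower(trimws(x)), tolower(SUBTYPE_LEVELS))
  out <- SUBTYPE_LEVELS[idx]
  out[is.na(idx) & !is.na(x) & trimws(x) != ""] <- "non-classified"
  out
}
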