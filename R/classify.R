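#' Nearest-centroid molecular subtype classification (SSP)
#'
#' Single-sample-predictor classification: each expression profile is
#' correlated (Pearson) with every subtype centroid over the genes shared
#' between the expression matrix and the centroid table, and assigned to the
#' best-correlated subtype; a sample whose correlations to all centroids fall
#' below `cutoff` is left "non-classified".
#'
#' Probes are collapsed to genes before matching (per-gene mean by default),
#' and symbols are matched after upper-casing.
#'
#' @param expr an [expression_matrix].
#' @param centroids numeric gene-by-subtype matrix, as from [read_centroids].
#' @param cutoff minimum Pearson correlation for assignment (default 0.2).
#' @param collapse how to collapse multiple probes of one gene: `"mean"`
#'   (default) or `"first"` (first probe in matrix order).
#' @return A data.frame with one row per sample: `sample_id`, one correlation
#'   column `r_<subtype>` per centroid, `best_subtype`, and `assigned`
#'   (the best subtype, or `"non-classified"`).
#' @export
classify_ssp <- function(expr, centroids, cutoff = 0.2,
                         collapse = c("mean", "first")) {
  collapse <- match.arg(collapse)
  gv <- collapse_probes(expr, collapse)
  cent_genes <- norm_symbol(rownames(centroids))
  shared <- intersect(rownames(gv), cent_genes)
  dropped <- (nrow(gv) - length(shared)) + (length(cent_genes) -
                                              length(shared))
  if (length(shared) < 10L)
    stop("fewer than 10 genes shared with the centroid set", call. = FALSE)
  if (dropped > 0L)
    message(dropped, " gene(s) not shared between expression data and ",
            "centroids; dropped")
  gv <- gv[shared, , drop = FALSE]
  cm <- centroids[match(shared, cent_genes), , drop = FALSE]
  subtypes <- colnames(centroids)
  res <- lapply(seq_len(ncol(gv)), function(j) {
    x <- gv[, j]
    r <- vapply(seq_along(subtypes), function(s) {
      ok <- !is.na(x) & !is.na(cm[, s])
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(cm[ok, s]) == 0)
        return(NA_real_)
      stats::cor(x[ok], cm[ok, s])
    }, numeric(1L))
    best_i <- which(r == max(r, na.rm = TRUE))[1L]
    if (sum(r == max(r, na.rm = TRUE), na.rm = TRUE) > 1L)
      message("tie at argmax for sample ", colnames(gv)[j],
              "; first centroid in column order used")
    assigned <- if (!is.na(r[best_i]) && r[best_i] >= cutoff)
      subtypes[best_i] else "non-classified"
    c(list(sample_id = colnames(gv)[j]),
      stats::setNames(as.list(r), paste0("r_", subtypes)),
      list(best_subtype = subtypes[best_i], assigned = assigned))
  })
  out <- do.call(rbind, lapply(res, function(z)
    as.data.frame(z, stringsAsFactors = FALSE, check.names = FALSE)))
  attr(out, "cutoff") <- cutoff
  out
}

# probe -> gene collapse; returns gene x sample matrix with upper-cased
# symbols as rownames
collapse_probes <- function(expr, collapse = c("mean", "first")) {
  collapse <- match.arg(collapse)
  genes <- norm_symbol(expr$gene)
  if (collapse == "first") {
    keep <- !duplicated(genes)
    gv <- expr$values[keep, , drop = FALSE]
    rownames(gv) <- genes[keep]
    return(gv)
  }
  ug <- unique(genes)
  gv <- matrix(NA_real_, length(ug), ncol(expr$values),
               dimnames = list(ug, colnames(expr$values)))
  for (g in ug)
    gv[g, ] <- colMeans(expr$values[genes == g, , drop = FALSE], na.rm = TRUE)
  gv[is.nan(gv)] <- NA_real_
  gv
}
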