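#' Stratify beta-values into ternary methylation calls
#'
#' Maps each beta-value onto three methylation states: values at or below
#' `t_low` become 0 (unmethylated), values strictly between the thresholds
#' become 0.5 (hemimethylated), and values at or above `t_high` become 1 and
#' are interpreted as hypermethylated. Missing values stay missing.
#'
#' @param beta a [beta_matrix] (a [ternary_matrix] is accepted too, making the
#'   operation idempotent).
#' @param t_low,t_high stratification thresholds, `0 < t_low < t_high < 1`
#'   (defaults 0.3 and 0.7).
#' @return A [ternary_matrix] on the same grid.
#' @export
stratify <- function(beta, t_low = 0.3, t_high = 0.7) {
  stopifnot(inherits(beta, c("beta_matrix", "ternary_matrix")))
  if (!(t_low > 0 && t_high < 1 && t_low < t_high))
    stop("thresholds must satisfy 0 < t_low < t_high < 1", call. = FALSE)
  v <- beta$values
  out <- ifelse(v <= t_low, 0, ifelse(v >= t_high, 1, 0.5))
  ternary_matrix(out, beta$gene)
}

#' Per-sample methylation frequency
#'
#' The methylation frequency of a sample is the fraction of its informative
#' (non-missing) CpG sites with stratified value 1, optionally restricted to a
#' subset of CpG sites (e.g. a subtype-associated panel).
#'
#' @param tern a [ternary_matrix].
#' @param cpg_subset optional character vector of CpG ids to restrict to.
#' @return A data.frame with columns `sample_id`, `methylation_frequency`
#'   and `n_informative`.
#' @export
methylation_frequency <- function(tern, cpg_subset = NULL) {
  stopifnot(inherits(tern, "ternary_matrix"))
  v <- tern$values
  if (!is.null(cpg_subset)) {
    if (length(cpg_subset) == 0L)
      stop("'cpg_subset' must be non-empty", call. = FALSE)
    missing_ids <- setdiff(cpg_subset, rownames(v))
    if (length(missing_ids))
      stop("unknown CpG id in subset: ", missing_ids[1L], call. = FALSE)
    v <- v[cpg_subset, , drop = FALSE]
  }
  n_inf <- colSums(!is.na(v))
  freq <- colSums(v == 1, na.rm = TRUE) / n_inf
  data.frame(sample_id = colnames(v),
             methylation_frequency = unname(freq),
             n_informative = unname(n_inf),
             stringsAsFactors = FALSE)
}

#' Mean-centre ternary values to relative methylation levels
#'
#' Subtracts from each CpG row its mean over the centring sample set
#' (conventionally all tumour samples). Samples outside the centring set
#' (e.g. normal tissue) are centred with the same tumour-derived mean, so
#' their relative levels are comparable to the tumours'.
#'
#' @param tern a [ternary_matrix].
#' @param centring_samples character vector of sample ids used to compute the
#'   per-CpG means; defaults to all samples.
#' @return A [relative_matrix] on the same grid.
#' @export
centre <- function(tern, centring_samples = colnames(tern$values)) {
  stopifnot(inherits(tern, "ternary_matrix"))
  if (length(centring_samples) == 0L)
    stop("'centring_samples' must be non-empty", call. = FALSE)
  missing_ids <- setdiff(centring_samples, colnames(tern$values))
  if (length(missing_ids))
    stop("unknown sample id in centring set: ", missing_ids[1L],
         call. = FALSE)
  v <- tern$values
  m <- rowMeans(v[, centring_samples, drop = FALSE], na.rm = TRUE)
  dead <- !is.finite(m)
  if (any(dead)) {
    warning(sum(dead), " CpG(s) with no informative value in the centring ",
            "set; set to all-missing", call. = FALSE)
    m[dead] <- NA_real_
  }
  relative_matrix(v - m, tern$gene)
}

#' Keep the most variably methylated CpG sites
#'
#' Retains CpG rows whose sample standard deviation (denominator n - 1, over
#' non-missing values) is at least `sd_min`. Because centring shifts a row by
#' a constant, the filter gives identical results on ternary and relative
#' values.
#'
#' @param rel a [relative_matrix] (or [ternary_matrix]).
#' @param sd_min minimum sample standard deviation (default 0.3).
#' @return The input container restricted to the retained CpG rows.
#' @export
filter_variable <- function(rel, sd_min = 0.3) {
  stopifnot(inherits(rel, c("relative_matrix", "ternary_matrix")))
  sds <- apply(rel$values, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds >= sd_min
  subset_meth_matrix(rel, features = which(keep))
}
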