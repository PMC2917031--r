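#' Match CpG sites to expression probes by gene symbol
#'
#' Builds the full cross product, within each gene symbol, of CpG sites from
#' the methylation matrix and probes from the expression matrix. Symbols are
#' upper-cased and whitespace-stripped before matching; no alias resolution is
#' attempted.
#'
#' @param rel a [relative_matrix] (or any methylation container).
#' @param expr an [expression_matrix].
#' @return A `pair_table` data.frame with columns `cpg_id`, `probe_id`,
#'   `gene`; the shared sample ids are attached as attribute `samples`.
#' @export
match_pairs <- function(rel, expr) {
  shared <- intersect(colnames(rel$values), colnames(expr$values))
  if (length(shared) < 2L)
    stop("methylation and expression matrices share fewer than 2 samples",
         call. = FALSE)
  cpg_gene <- norm_symbol(rel$gene)
  probe_gene <- norm_symbol(expr$gene)
  genes <- intersect(unique(cpg_gene), unique(probe_gene))
  out <- lapply(genes, function(g) {
    expand.grid(cpg_id = names(cpg_gene)[cpg_gene == g],
                probe_id = names(probe_gene)[probe_gene == g],
                stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(pairs))
    pairs <- data.frame(cpg_id = character(), probe_id = character())
  pairs$gene <- cpg_gene[pairs$cpg_id]
  rownames(pairs) <- NULL
  attr(pairs, "samples") <- shared
  class(pairs) <- c("pair_table", "data.frame")
  pairs
}

#' Correlate methylation with expression for each matched pair
#'
#' Pearson correlation over pairwise-complete shared samples for every
#' CpG-probe pair. Pairs whose relative methylation does not change across
#' the shared samples are flagged `"constant-methylation"` (no correlation is
#' defined for them); pairs with fewer than 3 complete samples are flagged
#' `"insufficient"`. Both flags exclude a pair from the sign test.
#'
#' @param pairs a `pair_table` from [match_pairs].
#' @param rel the [relative_matrix] the pairs were built from.
#' @param expr the [expression_matrix] the pairs were built from.
#' @return The pair table with columns `r`, `n_samples` and `flag`
#'   (`"ok"`, `"constant-methylation"`, `"constant-expression"`,
#'   `"insufficient"`).
#' @export
pair_correlations <- function(pairs, rel, expr) {
  shared <- attr(pairs, "samples")
  m <- rel$values[pairs$cpg_id, shared, drop = FALSE]
  e <- expr$values[pairs$probe_id, shared, drop = FALSE]
  n <- nrow(pairs)
  r <- rep(NA_real_, n)
  n_used <- integer(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    ok <- !is.na(m[i, ]) & !is.na(e[i, ])
    n_used[i] <- sum(ok)
    if (n_used[i] < 3L) {
      flag[i] <- "insufficient"
    } else if (stats::sd(m[i, ok]) == 0) {
      flag[i] <- "constant-methylation"
    } else if (stats::sd(e[i, ok]) == 0) {
      flag[i] <- "constant-expression"
    } else {
      r[i] <- stats::cor(m[i, ok], e[i, ok])
      flag[i] <- "ok"
    }
  }
  pairs$r <- r
  pairs$n_samples <- n_used
  pairs$flag <- flag
  pairs
}

#' Exact binomial sign test for inverse methylation-expression correlation
#'
#' Among the pairs with varying methylation (flag `"ok"`), counts those with a
#' negative correlation coefficient and applies a two-sided exact binomial
#' test at success probability 0.5 (the "minlike" two-sided convention of
#' `stats::binom.test`: all outcomes with point probability at most that of
#' the observed count are summed). A correlation of exactly 0 counts as
#' non-negative.
#'
#' @param pairs a `pair_table` with correlations from [pair_correlations],
#'   or a list/data.frame with an `r` column and optionally a `flag` column.
#' @return A list with `n_varying`, `n_negative`, `fraction_negative` and
#'   `p_value`.
#' @export
sign_test <- function(pairs) {
  r <- pairs$r
  if (!is.null(pairs$flag)) r <- r[pairs$flag == "ok"]
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no varying pairs to test", call. = FALSE)
  if (any(r == 0))
    message(sum(r == 0), " pair(s) with r exactly 0 counted as non-negative")
  n_neg <- sum(r < 0)
  n <- length(r)
  list(n_varying = n,
       n_negative = n_neg,
       fraction_negative = n_neg / n,
       p_value = stats::binom.test(n_neg, n, p = 0.5,
                                   alternative = "two.sided")$p.value)
}
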