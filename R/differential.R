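#' @section Permutation machinery:
#' Both differential procedures share one permutation scheme: the sample
#' labels are permuted as a block (the same permutation applied to every CpG
#' row), which preserves the between-CpG correlation structure under the null.
#' @name differential
#' @keywords internal
NULL

# Row-wise one-way ANOVA F statistics, vectorised over CpGs.
# values: CpG x sample matrix (NA allowed); groups: factor over columns.
row_f_stats <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  X <- stats::model.matrix(~ groups - 1)
  W <- !is.na(values)
  V0 <- values
  V0[!W] <- 0
  counts <- W %*% X                      # per-CpG per-group n
  sums <- V0 %*% X
  n_i <- rowSums(W)
  grand <- rowSums(V0) / n_i
  m_g <- sums / counts                   # NaN where a group is empty for a CpG
  ssb <- rowSums(counts * (m_g - grand)^2, na.rm = TRUE)
  sst <- rowSums(W * (V0 - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n_i - k
  f <- (ssb / df1) / (ssw / df2)
  f[ssw == 0 & ssb == 0] <- 0            # fully constant row
  f[ssw == 0 & ssb > 0] <- Inf
  f
}

# Permutations of the column indices 1..n: a B x n matrix of random
# permutations, or all n! permutations when exact.
permutation_matrix <- function(n, n_perm, exact = FALSE) {
  if (exact) {
    all_perms <- function(v) {
      if (length(v) <= 1L) return(matrix(v, nrow = 1L))
      do.call(rbind, lapply(seq_along(v), function(i) {
        cbind(v[i], all_perms(v[-i]))
      }))
    }
    if (n > 8L) stop("exact enumeration limited to 8 samples", call. = FALSE)
    return(all_perms(seq_len(n)))
  }
  t(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)))
}

#' Permutation one-way ANOVA with false-significant-number control
#'
#' Per CpG, the one-way F statistic of relative methylation across the sample
#' groups; its null distribution is obtained from label permutations shared
#' across CpGs. Each CpG's permutation p-value is the fraction of null F
#' values at or above the observed one. For every candidate p-value cutoff,
#' the false significant number FSN(cut) is the mean, over permutations, of
#' the number of CpGs whose *permuted* p-value falls at or below the cutoff;
#' the procedure returns the largest selection whose FSN does not exceed
#' `fsn_max` and reports the implied FDR = FSN / n selected.
#'
#' @param rel a [relative_matrix].
#' @param groups group labels aligned with the sample columns (named vectors
#'   are matched by sample id); samples with missing labels are dropped.
#' @param n_perm number of label permutations (default 1000).
#' @param fsn_max largest tolerated false significant number (default 10).
#' @param seed integer seed for the permutation draw.
#' @param exact enumerate all label permutations instead of sampling
#'   (feasible up to 8 samples); `n_perm` is then ignored.
#' @param adjust `"none"` (raw permutation p, default) or `"bonferroni"`
#'   applied before the cutoff sweep.
#' @return A `diff_result` list: per-CpG `statistic` (F) and `p_value`,
#'   logical `selected`, the p-value `cutoff` used, `achieved_fsn`,
#'   `implied_fdr`, `n_perm`, `fsn_max` and `seed`.
#' @export
permutation_anova <- function(rel, groups, n_perm = 1000L, fsn_max = 10,
                              seed, exact = FALSE,
                              adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  v <- rel$values
  if (!is.null(names(groups))) groups <- groups[colnames(v)]
  keep <- !is.na(groups)
  v <- v[, keep, drop = FALSE]
  groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  if (!exact && n_perm < 100L)
    warning("fewer than 100 permutations gives a coarse null", call. = FALSE)
  if (!exact) {
    if (missing(seed)) stop("'seed' is required", call. = FALSE)
    set.seed(seed)
  } else seed <- NA_integer_
  n <- ncol(v)
  perms <- permutation_matrix(n, n_perm, exact)
  B <- nrow(perms)
  f_obs <- row_f_stats(v, groups)
  f_null <- matrix(NA_real_, nrow(v), B)
  for (b in seq_len(B))
    f_null[, b] <- row_f_stats(v[, perms[b, ], drop = FALSE], groups)
  # observed permutation p: add-one for sampled permutations; plain fraction
  # for the exhaustive null (which contains the identity)
  ge_obs <- rowSums(f_null >= f_obs)
  p_obs <- if (exact) ge_obs / B else (ge_obs + 1) / (B + 1)
  # permuted p-values: within each CpG's null, the upper-tail rank fraction
  p_null <- t(apply(f_null, 1L, function(z) {
    (length(z) + 1 - rank(z, ties.method = "min")) / length(z)
  }))
  if (adjust == "bonferroni") {
    p_obs <- pmin(p_obs * nrow(v), 1)
    p_null <- pmin(p_null * nrow(v), 1)
  }
  # sweep candidate cutoffs = observed p values, largest selection first
  cand <- sort(unique(p_obs), decreasing = TRUE)
  null_sorted <- sort(as.vector(p_null))
  cutoff <- NA_real_
  achieved <- 0
  for (cut in cand) {
    fsn <- findInterval(cut, null_sorted) / B
    if (fsn <= fsn_max) {
      cutoff <- cut
      achieved <- fsn
      break
    }
  }
  selected <- if (is.na(cutoff)) rep(FALSE, nrow(v)) else p_obs <= cutoff
  names(selected) <- rownames(v)
  structure(list(statistic = stats::setNames(f_obs, rownames(v)),
                 p_value = stats::setNames(p_obs, rownames(v)),
                 selected = selected,
                 cutoff = cutoff,
                 achieved_fsn = achieved,
                 implied_fdr = if (any(selected)) achieved / sum(selected)
                               else 0,
                 n_perm = B, fsn_max = fsn_max, seed = seed,
                 procedure = "permutation_anova"),
            class = "diff_result")
}

# SAM relative difference d = (mean_in - mean_out) / (s + s0) with s the
# Tusher pooled standard error; returns list(r, s) per CpG.
sam_components <- function(values, in_mask) {
  v_in <- values[, in_mask, drop = FALSE]
  v_out <- values[, !in_mask, drop = FALSE]
  n1 <- rowSums(!is.na(v_in))
  n2 <- rowSums(!is.na(v_out))
  m1 <- rowMeans(v_in, na.rm = TRUE)
  m2 <- rowMeans(v_out, na.rm = TRUE)
  ss1 <- rowSums((v_in - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((v_out - m2)^2, na.rm = TRUE)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(r = m1 - m2, s = sqrt(a * (ss1 + ss2)))
}

# Tusher-style exchangeability factor: the s-quantile minimising the
# coefficient of variation of the spread of d across s-percentile windows.
sam_s0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  s_alpha <- stats::quantile(s, alphas, names = FALSE)
  windows <- cut(s, breaks = unique(stats::quantile(
    s, seq(0, 1, by = 0.05), names = FALSE)), include.lowest = TRUE)
  cv <- vapply(s_alpha, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, windows, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  s0 <- if (all(is.na(cv))) stats::quantile(s, 0.05, names = FALSE)
        else s_alpha[which.min(cv)]
  # a zero factor would leave d undefined for zero-error features
  if (s0 == 0) {
    pos <- s[s > 0]
    s0 <- if (length(pos)) stats::quantile(pos, 0.05, names = FALSE) else 1
  }
  s0
}

#' SAM-style two-class permutation test
#'
#' Per CpG, the SAM relative difference `d = (mean_in - mean_out) / (s + s0)`,
#' with `s` the pooled standard error and `s0` an exchangeability factor
#' chosen to minimise the coefficient of variation of d's spread across
#' windows of `s`. The observed order statistics `d_(i)` are compared with
#' their permutation expectations `dbar_(i)`; for a threshold `delta`, the
#' positive cut is the smallest non-negative `d_(i)` with
#' `d_(i) - dbar_(i) >= delta` (symmetrically for the negative cut), and
#' every CpG beyond a cut is called. The returned `delta` is the smallest
#' whose median permuted false-call count, divided by the number of calls,
#' does not exceed `target_fdr` (0 by default: the median permuted false-call
#' count must be 0).
#'
#' @param rel a [relative_matrix].
#' @param in_group character vector of sample ids forming the "in" class
#'   (e.g. one molecular subtype); all other columns form the "out" class.
#' @param n_perm number of class-label permutations (default 1000).
#' @param target_fdr target median-based false discovery rate (default 0).
#' @param seed integer seed for the permutation draw.
#' @param exact enumerate all assignments of the class labels (feasible for
#'   small samples); `n_perm` is then ignored.
#' @param false_call summary of the per-permutation false-call counts used
#'   in the FDR criterion: `"median"` (default) or `"mean"`. At a target of
#'   0 the mean is the stricter reading — zero *expected* false calls — and
#'   suppresses the occasional lone extreme call the median rule lets
#'   through on null data.
#' @return A `diff_result` list: per-CpG `statistic` (d), `selected`,
#'   `direction` (+1 hypermethylated in the in-class, -1 hypomethylated, 0
#'   not called), `s0`, `delta`, `cut_up`, `cut_low`,
#'   `median_false_calls`, `implied_fdr`, `n_perm` and `seed`.
#' @export
sam_two_class <- function(rel, in_group, n_perm = 1000L, target_fdr = 0,
                          seed, exact = FALSE,
                          false_call = c("median", "mean")) {
  false_call <- match.arg(false_call)
  v <- rel$values
  in_mask <- colnames(v) %in% in_group
  n1 <- sum(in_mask)
  n2 <- sum(!in_mask)
  if (n1 < 2L || n2 < 2L)
    stop("both classes need at least 2 samples", call. = FALSE)
  comp <- sam_components(v, in_mask)
  if (any(comp$s == 0))
    message(sum(comp$s == 0),
            " CpG(s) with zero pooled error; d defined via s0 only")
  s0 <- sam_s0(comp$r, comp$s)
  d_obs <- comp$r / (comp$s + s0)
  n <- ncol(v)
  if (exact) {
    sets <- utils::combn(n, n1)
    B <- ncol(sets)
    seed <- NA_integer_
  } else {
    if (missing(seed)) stop("'seed' is required", call. = FALSE)
    set.seed(seed)
    sets <- vapply(seq_len(n_perm), function(b) sample.int(n, n1),
                   integer(n1))
    B <- n_perm
  }
  d_null <- matrix(NA_real_, nrow(v), B)
  for (b in seq_len(B)) {
    mask <- logical(n)
    mask[sets[, b]] <- TRUE
    cb <- sam_components(v, mask)
    d_null[, b] <- cb$r / (cb$s + s0)
  }
  ord <- order(d_obs)
  d_sorted <- d_obs[ord]
  dbar <- rowMeans(apply(d_null, 2L, sort))
  diffs <- d_sorted - dbar
  # candidate thresholds: every observed deviation from the expected order
  # statistics, smallest first
  cand <- sort(unique(c(0, abs(diffs))))
  pick <- NULL
  for (delta in cand) {
    up_idx <- which(diffs >= delta & d_sorted >= 0)
    low_idx <- which(-diffs >= delta & d_sorted <= 0)
    cut_up <- if (length(up_idx)) min(d_sorted[up_idx]) else Inf
    cut_low <- if (length(low_idx)) max(d_sorted[low_idx]) else -Inf
    called <- d_obs >= cut_up | d_obs <= cut_low
    n_called <- sum(called)
    # per-permutation false calls beyond the cuts; median over permutations
    false_per_perm <- if (n_called == 0L) rep(0, B) else
      colSums(d_null >= cut_up) + colSums(d_null <= cut_low)
    med_false <- if (false_call == "median") stats::median(false_per_perm)
                 else mean(false_per_perm)
    fdr <- if (n_called == 0L) 0 else med_false / n_called
    if (fdr <= target_fdr) {
      pick <- list(delta = delta, cut_up = cut_up, cut_low = cut_low,
                   called = called, med_false = med_false, fdr = fdr)
      break
    }
  }
  if (is.null(pick))
    pick <- list(delta = Inf, cut_up = Inf, cut_low = -Inf,
                 called = rep(FALSE, length(d_obs)), med_false = 0, fdr = 0)
  direction <- integer(length(d_obs))
  direction[pick$called & d_obs > 0] <- 1L
  direction[pick$called & d_obs < 0] <- -1L
  structure(list(statistic = stats::setNames(d_obs, rownames(v)),
                 selected = stats::setNames(pick$called, rownames(v)),
                 direction = stats::setNames(direction, rownames(v)),
                 s0 = s0, delta = pick$delta,
                 cut_up = pick$cut_up, cut_low = pick$cut_low,
                 median_false_calls = pick$med_false,
                 implied_fdr = pick$fdr,
                 expected_order = dbar,
                 n_perm = B, target_fdr = target_fdr, seed = seed,
                 procedure = "sam_two_class"),
            class = "diff_result")
}

#' Methylation frequency summarised by annotation group
#'
#' For a CpG panel (typically the subtype-associated CpGs), computes each
#' sample's methylation frequency over the panel, then the per-level mean,
#' SD and n for a chosen annotation field, with an ANOVA p-value across
#' levels (t-test when exactly two levels).
#'
#' @param tern a [ternary_matrix].
#' @param cpg_subset character vector of CpG ids defining the panel.
#' @param annotation data.frame as from [read_annotation].
#' @param field annotation column to stratify by.
#' @param drop_levels levels omitted from the comparison (default
#'   `"unknown"`); levels with no samples are omitted automatically.
#' @return A list with `table` (data.frame: `level`, `mean_frequency`,
#'   `sd_frequency`, `n`), `p_value` and `test`.
#' @export
frequency_by_group <- function(tern, cpg_subset, annotation, field,
                               drop_levels = "unknown") {
  freq <- methylation_frequency(tern, cpg_subset)
  ann <- annotation[match(freq$sample_id, annotation$sample_id), ,
                    drop = FALSE]
  lv <- ann[[field]]
  keep <- !is.na(lv) & !(lv %in% drop_levels)
  x <- freq$methylation_frequency[keep]
  lv <- lv[keep]
  tab <- do.call(rbind, lapply(unique(lv), function(g) {
    data.frame(level = g, mean_frequency = mean(x[lv == g]),
               sd_frequency = stats::sd(x[lv == g]), n = sum(lv == g),
               stringsAsFactors = FALSE)
  }))
  test <- if (length(unique(lv)) == 2L) "t" else "anova"
  gc <- group_compare(x, lv, test = test)
  list(table = tab, p_value = gc$p_value, statistic = gc$statistic,
       test = test)
}
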