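#' Pearson correlation distance
#'
#' `d = 1 - r`, with `r` the Pearson correlation over pairwise-complete
#' positions, so `d` lies in \[0, 2\].
#'
#' @param x,y numeric vectors of equal length with at least 3 paired
#'   non-missing positions.
#' @return The distance, a scalar in \[0, 2\].
#' @export
pearson_distance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("need at least 3 paired non-missing positions", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  1 - stats::cor(x, y)
}

# sample-by-sample Pearson distance matrix over the columns of `values`
pearson_distance_matrix <- function(values) {
  r <- suppressWarnings(stats::cor(values, use = "pairwise.complete.obs"))
  if (anyNA(r))
    stop("correlation undefined for a constant sample profile", call. = FALSE)
  1 - r
}

#' Hierarchical clustering of samples (UPGMA, Pearson distance)
#'
#' Agglomerates samples by unweighted average linkage (UPGMA) on the Pearson
#' correlation distance between their methylation profiles, then cuts the tree
#' into `cut_k` groups.
#'
#' @param rel a [relative_matrix] (any of the matrix containers works).
#' @param cut_k number of clusters to cut the tree into (>= 2).
#' @return A `cluster_result`: list with `assignments` (named integer vector
#'   of cluster labels), `method`, `k`, `merge` (data.frame of merges with
#'   `node1`, `node2`, `height`; negative node numbers are leaves, in hclust
#'   convention), and the `hclust` object as `tree`.
#' @export
hierarchical_cluster <- function(rel, cut_k) {
  if (cut_k < 2L) stop("'cut_k' must be at least 2", call. = FALSE)
  if (ncol(rel$values) < cut_k)
    stop("fewer samples than requested clusters", call. = FALSE)
  d <- pearson_distance_matrix(rel$values)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  assignments <- stats::cutree(hc, k = cut_k)
  structure(list(assignments = assignments,
                 method = "hierarchical",
                 k = cut_k,
                 merge = data.frame(node1 = hc$merge[, 1L],
                                    node2 = hc$merge[, 2L],
                                    height = hc$height),
                 tree = hc,
                 seed = NA_integer_),
            class = "cluster_result")
}

#' K-means clustering of samples under Pearson distance
#'
#' Lloyd-style iteration with the Pearson correlation distance: each sample is
#' assigned to the centroid it is least distant from; each centroid is the
#' per-CpG mean of its members. The best of `restarts` random initialisations
#' (by total within-cluster distance) is returned. An emptied cluster is
#' re-seeded from the sample farthest from its current centroid.
#'
#' @param rel a [relative_matrix].
#' @param k number of clusters, `1 <= k <=` number of samples.
#' @param restarts number of random restarts (default 50).
#' @param seed integer seed; the run is fully reproducible from it.
#' @param max_iter iteration cap per restart.
#' @return A `cluster_result` with `assignments`, `method = "kmeans"`, `k`,
#'   `within` (total within-cluster distance of the returned solution) and
#'   `seed`.
#' @export
kmeans_cluster <- function(rel, k, restarts = 50L, seed, max_iter = 100L) {
  v <- rel$values
  n <- ncol(v)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of samples",
                            call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- kmeans_once(v, k, max_iter)
    if (is.null(best) || fit$within < best$within) best <- fit
  }
  structure(list(assignments = stats::setNames(best$assignments, colnames(v)),
                 method = "kmeans", k = k, within = best$within,
                 seed = seed),
            class = "cluster_result")
}

kmeans_once <- function(v, k, max_iter) {
  n <- ncol(v)
  centroids <- v[, sample.int(n, k), drop = FALSE]
  assignments <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d <- 1 - suppressWarnings(stats::cor(v, centroids,
                                         use = "pairwise.complete.obs"))
    d[is.na(d)] <- 2  # constant profiles are maximally distant
    new_assign <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        # re-seed an emptied cluster from the globally farthest sample
        far <- which.max(d[cbind(seq_len(n), new_assign)])
        message("k-means: re-seeding emptied cluster ", j,
                " from sample ", colnames(v)[far])
        new_assign[far] <- j
      }
    }
    if (identical(new_assign, assignments)) break
    assignments <- new_assign
    for (j in seq_len(k))
      centroids[, j] <- rowMeans(v[, assignments == j, drop = FALSE],
                                 na.rm = TRUE)
  }
  d <- 1 - suppressWarnings(stats::cor(v, centroids,
                                       use = "pairwise.complete.obs"))
  d[is.na(d)] <- 2
  within <- sum(d[cbind(seq_len(n), assignments)])
  list(assignments = assignments, within = within)
}

#' Associate clusters with a sample annotation
#'
#' For each (cluster, annotation level) pair, builds the 2x2 contingency table
#' "in / out of cluster" versus "is / is not the level" over the tested
#' samples and applies a two-sided Fisher's exact test. For the `subtype`
#' annotation, samples labelled non-classified or non-GEX are excluded
#' entirely by default, mirroring an analysis restricted to
#' expression-classified tumours.
#'
#' @param clusters a `cluster_result`.
#' @param annotation data.frame as from [read_annotation].
#' @param category annotation column to test (default `"subtype"`).
#' @param restrict_to optional character vector of sample ids to restrict the
#'   test to.
#' @param drop_levels annotation levels excluded entirely (samples dropped);
#'   defaults to `c("non-classified", "non-GEX", "unknown")`.
#' @return A data.frame with one row per (cluster, level): the 2x2 counts
#'   `n11` (in cluster, is level), `n12`, `n21`, `n22`, the conditional
#'   odds-ratio estimate and the two-sided Fisher p-value.
#' @export
associate_clusters <- function(clusters, annotation, category = "subtype",
                               restrict_to = NULL,
                               drop_levels = c("non-classified", "non-GEX",
                                               "unknown")) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (!category %in% names(annotation))
    stop("annotation has no column '", category, "'", call. = FALSE)
  ann <- annotation[match(names(clusters$assignments),
                          annotation$sample_id), , drop = FALSE]
  keep <- !is.na(ann$sample_id)
  if (!is.null(restrict_to))
    keep <- keep & names(clusters$assignments) %in% restrict_to
  labels <- ann[[category]]
  keep <- keep & !is.na(labels) & !(labels %in% drop_levels)
  cl <- clusters$assignments[keep]
  labels <- labels[keep]
  levels_tested <- unique(labels)
  out <- list()
  for (g in sort(unique(cl))) {
    for (lv in levels_tested) {
      in_cl <- cl == g
      is_lv <- labels == lv
      tab <- matrix(c(sum(in_cl & is_lv), sum(in_cl & !is_lv),
                      sum(!in_cl & is_lv), sum(!in_cl & !is_lv)),
                    2L, 2L, byrow = TRUE)
      ft <- stats::fisher.test(tab)
      out[[length(out) + 1L]] <- data.frame(
        cluster = g, level = lv,
        n11 = tab[1L, 1L], n12 = tab[1L, 2L],
        n21 = tab[2L, 1L], n22 = tab[2L, 2L],
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare a numeric variable between sample groups
#'
#' Two-sided classical tests on a per-sample quantity (e.g. methylation
#' frequency or a gene-set score): one-way equal-variance ANOVA, a two-sample
#' t-test (Welch by default, pooled-variance optionally), or the Wilcoxon
#' rank-sum test (exact when both groups have at most 25 untied values,
#' normal approximation with continuity correction otherwise).
#'
#' @param values numeric vector, one value per sample.
#' @param groups vector of group labels aligned with `values`.
#' @param test one of `"anova"`, `"t"`, `"wilcoxon"`.
#' @param var_equal for `test = "t"`, pool the variances (default `FALSE`,
#'   Welch).
#' @return A list with `statistic`, `p_value`, `test`, and `df` where defined.
#' @export
group_compare <- function(values, groups, test = c("anova", "t", "wilcoxon"),
                          var_equal = FALSE) {
  test <- match.arg(test)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (any(sizes == 0L) || nlevels(groups) < 2L)
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (test == "anova") {
    if (any(sizes < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
    ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "anova", df = unname(ht$parameter))
  } else if (test == "t") {
    if (nlevels(groups) != 2L) stop("t-test needs exactly 2 groups",
                                    call. = FALSE)
    if (any(sizes < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
    ht <- stats::t.test(values ~ groups, var.equal = var_equal)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "t", df = unname(ht$parameter))
  } else {
    if (nlevels(groups) != 2L) stop("wilcoxon needs exactly 2 groups",
                                    call. = FALSE)
    x <- values[groups == levels(groups)[1L]]
    y <- values[groups == levels(groups)[2L]]
    ties <- any(duplicated(c(x, y)))
    use_exact <- max(length(x), length(y)) <= 25L && !ties
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "wilcoxon", df = NULL)
  }
}
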