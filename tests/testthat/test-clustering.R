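test_that("pearson distance matches the covariance/SD formula", {
  expect_equal(pearson_distance(1:5, 1:5), 0, tolerance = 1e-12)
  x <- c(1, 2, 3, 4) - 2.5
  expect_equal(pearson_distance(x, -x), 2, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:5) {
    x <- stats::rnorm(10)
    y <- stats::rnorm(10)
    expect_equal(pearson_distance(x, y), pearson_distance_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(pearson_distance(rep(1, 5), stats::rnorm(5)), "constant")
  expect_error(pearson_distance(c(1, NA, 3), c(1, 2, NA)), "3 paired")
})

test_that("UPGMA reproduces a brute-force average-linkage oracle", {
  set.seed(42)
  for (rep in 1:3) {
    rel <- random_relative(25L, 8L, seed = 100 + rep)
    res <- hierarchical_cluster(rel, cut_k = 2L)
    d <- 1 - stats::cor(rel$values)
    oracle <- upgma_oracle(d)
    expect_equal(res$merge$height, oracle$heights, tolerance = 1e-10)
    # partitions after each merge agree (label-free comparison)
    for (k in 2:7) {
      got <- split(colnames(rel$values), stats::cutree(res$tree, k = k))
      want <- oracle$partitions[[8L - k]]
      expect_identical(canonical_partition(got), canonical_partition(want))
    }
  }
})

test_that("duplicated samples merge first at height zero", {
  rel <- random_relative(20L, 6L, seed = 55)
  rel$values[, "s2"] <- rel$values[, "s1"]
  res <- hierarchical_cluster(rel, cut_k = 2L)
  expect_equal(res$merge$height[1L], 0, tolerance = 1e-12)
  expect_setequal(abs(unlist(res$merge[1L, c("node1", "node2")])), c(1, 2))
  expect_error(hierarchical_cluster(rel, cut_k = 1L), "at least 2")
})

test_that("hierarchical clustering recovers planted subtype structure", {
  cfg <- simulation_config(
    n_cpgs = 300L, n_genes = 150L,
    subtype_sizes = c("basal-like" = 20L, "lumA" = 20L, "lumB" = 20L),
    baseline_meth = c("basal-like" = 0.30, "lumA" = 0.30, "lumB" = 0.30),
    n_normal = 0L, n_differential = 150L, differential_effect = 1,
    n_marker_genes = 10L, genesets = list(), seed = 73)
  sim <- simulate_study(cfg)
  rel <- centre(stratify(sim$beta))
  res <- hierarchical_cluster(filter_variable(rel), cut_k = 3L)
  ari <- mclust::adjustedRandIndex(
    res$assignments, sim$truth$sample_subtype[names(res$assignments)])
  expect_gt(ari, 0.9)
})

test_that("k-means under Pearson distance is reproducible and recovers
           planted groups", {
  cfg <- simulation_config(
    n_cpgs = 200L, n_genes = 100L,
    subtype_sizes = c("lumA" = 25L, "basal-like" = 25L),
    baseline_meth = c("lumA" = 0.30, "basal-like" = 0.30),
    n_normal = 0L, n_differential = 100L, differential_effect = 1,
    n_marker_genes = 10L, genesets = list(), seed = 74)
  sim <- simulate_study(cfg)
  rel <- filter_variable(centre(stratify(sim$beta)))
  r1 <- kmeans_cluster(rel, k = 2L, restarts = 10L, seed = 9)
  r2 <- kmeans_cluster(rel, k = 2L, restarts = 10L, seed = 9)
  expect_identical(r1$assignments, r2$assignments)

  truth <- sim$truth$sample_subtype[names(r1$assignments)]
  agreement <- max(mean((r1$assignments == 1L) == (truth == "lumA")),
                   mean((r1$assignments == 2L) == (truth == "lumA")))
  expect_gt(agreement, 0.95)

  r3 <- kmeans_cluster(rel, k = 1L, restarts = 2L, seed = 9)
  expect_equal(unname(r3$assignments), rep(1L, ncol(rel$values)))
  expect_error(kmeans_cluster(rel, k = 500L, seed = 1), "between 1")
})

test_that("every sample lands in exactly one cluster and sizes sum to n", {
  rel <- random_relative(30L, 12L, seed = 61)
  for (res in list(hierarchical_cluster(rel, 3L),
                   kmeans_cluster(rel, 3L, restarts = 5L, seed = 3))) {
    expect_identical(sort(names(res$assignments)),
                     sort(colnames(rel$values)))
    expect_equal(sum(table(res$assignments)), 12L)
  }
})

test_that("cluster-annotation Fisher tests match hypergeometric enumeration", {
  # balanced table: no association
  clusters <- structure(list(
    assignments = stats::setNames(rep(1:2, each = 10L), paste0("s", 1:20)),
    method = "kmeans", k = 2L), class = "cluster_result")
  ann <- data.frame(sample_id = paste0("s", 1:20),
                    subtype = rep(c("lumA", "lumB"), 10L),
                    stringsAsFactors = FALSE)
  res <- associate_clusters(clusters, ann)
  expect_equal(res$p_value, rep(1, 4L), tolerance = 1e-12)

  # perfect association and assorted margins against the oracle
  ann2 <- data.frame(sample_id = paste0("s", 1:20),
                     subtype = rep(c("lumA", "lumB"), each = 10L),
                     stringsAsFactors = FALSE)
  res2 <- associate_clusters(clusters, ann2)
  row <- res2[res2$cluster == 1L & res2$level == "lumA", ]
  expect_equal(row$p_value, fisher_p_oracle(10, 0, 0, 10), tolerance = 1e-10)
  for (tab in list(c(3, 7, 6, 4), c(1, 9, 9, 1), c(5, 0, 8, 7))) {
    expect_equal(stats::fisher.test(matrix(tab, 2L, byrow = TRUE))$p.value,
                 fisher_p_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
  # transposition symmetry of the 2x2 test
  expect_equal(fisher_p_oracle(3, 7, 6, 4), fisher_p_oracle(3, 6, 7, 4),
               tolerance = 1e-12)
})

test_that("the cluster capturing a planted subtype has the smallest p", {
  cfg <- simulation_config(
    n_cpgs = 200L, n_genes = 100L,
    subtype_sizes = c("lumA" = 20L, "lumB" = 20L, "basal-like" = 20L),
    baseline_meth = c("lumA" = 0.3, "lumB" = 0.3, "basal-like" = 0.3),
    n_normal = 0L, n_differential = 120L, differential_effect = 1,
    n_marker_genes = 10L, genesets = list(), seed = 75)
  sim <- simulate_study(cfg)
  rel <- filter_variable(centre(stratify(sim$beta)))
  res <- hierarchical_cluster(rel, cut_k = 3L)
  assoc <- associate_clusters(res, sim$annotation)
  truth <- sim$truth$sample_subtype
  lumb_cluster <- names(which.max(table(
    res$assignments[truth[names(res$assignments)] == "lumB"])))
  best <- assoc[which.min(assoc$p_value), ]
  hit <- assoc[assoc$cluster == lumb_cluster & assoc$level == "lumB", ]
  expect_equal(hit$p_value, min(assoc$p_value[assoc$level == "lumB"]))
  expect_lt(hit$p_value, 1e-6)
})

test_that("group comparisons reproduce closed-form t and the F = t^2 link", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3L)
  res <- group_compare(x, g, test = "t", var_equal = TRUE)
  # textbook pooled t for (1,2,3) vs (4,5,6): t = -3/sqrt(2/3)
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), df = 4),
               tolerance = 1e-12)
  aov_res <- group_compare(x, g, test = "anova")
  expect_equal(aov_res$statistic, res$statistic^2, tolerance = 1e-12)

  # zero between-group variance gives F = 0
  expect_equal(group_compare(c(1, 2, 1, 2), rep(c("a", "b"), each = 2L),
                             test = "anova")$statistic, 0)
  expect_error(group_compare(1:4, rep("a", 4L)), "2 non-empty groups")
  w <- group_compare(x, g, test = "wilcoxon")
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)  # exact rank-sum 3 vs 3
})
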