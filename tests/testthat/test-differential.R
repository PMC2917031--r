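test_that("the permutation ANOVA null matches exhaustive enumeration", {
  # 4 samples, 2 groups: all 24 column permutations
  rel <- random_relative(12L, 4L, seed = 81)
  groups <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  res <- permutation_anova(rel, groups, exact = TRUE)
  perms <- all_perms(4L)
  for (i in c(1L, 5L, 12L)) {
    f_obs <- f_stat_oracle(rel$values[i, ], groups)
    f_null <- apply(perms, 1L, function(p)
      f_stat_oracle(rel$values[i, p], groups))
    expect_equal(unname(res$statistic[i]), f_obs, tolerance = 1e-10)
    expect_equal(unname(res$p_value[i]), mean(f_null >= f_obs),
                 tolerance = 1e-10)
  }
})

test_that("SAM statistics match exhaustive enumeration for 3 vs 3", {
  rel <- random_relative(10L, 6L, seed = 82)
  in_group <- c("s1", "s2", "s3")
  res <- sam_two_class(rel, in_group, exact = TRUE)
  expect_equal(res$n_perm, choose(6, 3))
  in_mask <- colnames(rel$values) %in% in_group
  d_oracle <- vapply(seq_len(10L), function(i)
    sam_d_oracle(rel$values[i, ], in_mask, res$s0), numeric(1L))
  expect_equal(unname(res$statistic), d_oracle, tolerance = 1e-10)
  # expected order statistics from the full 20-assignment enumeration
  sets <- utils::combn(6L, 3L)
  d_null <- sapply(seq_len(ncol(sets)), function(b) {
    mask <- seq_len(6L) %in% sets[, b]
    sort(vapply(seq_len(10L), function(i)
      sam_d_oracle(rel$values[i, ], mask, res$s0), numeric(1L)))
  })
  expect_equal(res$expected_order, rowMeans(d_null), tolerance = 1e-10)
})

test_that("F and d are invariant under adding a constant to a CpG row", {
  rel <- random_relative(8L, 10L, seed = 83)
  groups <- stats::setNames(rep(c("a", "b"), each = 5L),
                            colnames(rel$values))
  shifted <- rel
  shifted$values[3L, ] <- shifted$values[3L, ] + 0.25
  a1 <- permutation_anova(rel, groups, n_perm = 100L, seed = 4)
  a2 <- permutation_anova(shifted, groups, n_perm = 100L, seed = 4)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-9)
  s1 <- sam_two_class(rel, paste0("s", 1:5), n_perm = 100L, seed = 4)
  s2 <- sam_two_class(shifted, paste0("s", 1:5), n_perm = 100L, seed = 4)
  expect_equal(s1$statistic[3L], s2$statistic[3L], tolerance = 1e-9)
})

test_that("permutation ANOVA is reproducible and seed-stable on strong
           effects", {
  cfg <- simulation_config(n_cpgs = 150L, n_genes = 75L,
                           subtype_sizes = c("lumA" = 20L, "lumB" = 20L),
                           baseline_meth = c("lumA" = 0.3, "lumB" = 0.3),
                           n_normal = 0L, n_differential = 40L,
                           differential_effect = 0.8, n_marker_genes = 10L,
                           genesets = list(), seed = 85)
  sim <- simulate_study(cfg)
  rel <- centre(stratify(sim$beta))
  groups <- sim$truth$sample_subtype
  r1 <- permutation_anova(rel, groups, n_perm = 300L, seed = 10)
  r2 <- permutation_anova(rel, groups, n_perm = 300L, seed = 10)
  expect_identical(r1$selected, r2$selected)
  r3 <- permutation_anova(rel, groups, n_perm = 300L, seed = 11)
  jaccard <- sum(r1$selected & r3$selected) / sum(r1$selected | r3$selected)
  expect_gte(jaccard, 0.9)
})

test_that("SAM makes no calls when the two classes share a distribution", {
  rel <- random_relative(100L, 20L, seed = 86)
  res <- sam_two_class(rel, paste0("s", 1:10), n_perm = 200L, seed = 12)
  expect_equal(res$median_false_calls, 0)
  expect_lte(sum(res$selected), 2L)
})

test_that("SAM recovers planted subtype-specific hypermethylation", {
  # 20 in-class vs 40 out-of-class samples, 30 hypermethylated CpGs
  set.seed(87)
  n_cpgs <- 200L
  v <- matrix(sample(c(-0.5, 0, 0.5), n_cpgs * 60L, replace = TRUE),
              n_cpgs, dimnames = list(paste0("c", seq_len(n_cpgs)),
                                      paste0("s", 1:60)))
  planted <- paste0("c", 1:30)
  v[planted, 1:20] <- v[planted, 1:20] + 0.5
  rel <- relative_matrix(v / 2, stats::setNames(
    paste0("g", seq_len(n_cpgs)), rownames(v)))
  res <- sam_two_class(rel, paste0("s", 1:20), n_perm = 300L, seed = 13)
  hyper <- names(res$direction)[res$direction == 1L]
  expect_gte(sum(planted %in% hyper), 27L)
  expect_equal(res$median_false_calls / max(sum(res$selected), 1L), 0)
})

test_that("the SAM call set shrinks monotonically as delta grows", {
  rel <- random_relative(80L, 16L, seed = 88)
  rel$values[1:10, 1:8] <- rel$values[1:10, 1:8] + 0.8
  res <- sam_two_class(rel, paste0("s", 1:8), n_perm = 150L, seed = 14)
  d_sorted <- sort(res$statistic)
  diffs <- d_sorted - res$expected_order
  called_at <- function(delta) {
    up <- which(diffs >= delta & d_sorted >= 0)
    low <- which(-diffs >= delta & d_sorted <= 0)
    cut_up <- if (length(up)) min(d_sorted[up]) else Inf
    cut_low <- if (length(low)) max(d_sorted[low]) else -Inf
    names(res$statistic)[res$statistic >= cut_up |
                           res$statistic <= cut_low]
  }
  deltas <- seq(0, 2, by = 0.25)
  sets <- lapply(deltas, called_at)
  for (i in seq_along(sets)[-1L])
    expect_true(all(sets[[i]] %in% sets[[i - 1L]]))
})

test_that("group frequency tables reproduce hand-computed summaries", {
  v <- matrix(c(1, 1, 0, 0,
                1, 0, 0, 0,
                1, 1, 1, 0), 3L, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:4)))
  tern <- ternary_matrix(v, stats::setNames(paste0("g", 1:3), rownames(v)))
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    subtype = c("lumB", "lumB", "basal-like", "basal-like"),
                    stringsAsFactors = FALSE)
  res <- frequency_by_group(tern, paste0("c", 1:3), ann, "subtype")
  tab <- res$table[order(res$table$level), ]
  # per-sample frequencies: s1 = 1, s2 = 2/3, s3 = 1/3, s4 = 0
  expect_equal(tab$mean_frequency[tab$level == "lumB"], 5 / 6,
               tolerance = 1e-12)
  expect_equal(tab$mean_frequency[tab$level == "basal-like"], 1 / 6,
               tolerance = 1e-12)
  expect_identical(res$test, "t")
  # groups with identical frequency distributions: t = 0 and p = 1
  v2 <- v
  v2[, 3:4] <- v2[, 1:2]
  ann$subtype <- c("lumA", "lumB", "lumB", "lumA")
  res2 <- frequency_by_group(ternary_matrix(v2, tern$gene),
                             paste0("c", 1:3), ann, "subtype")
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)
})
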