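test_that("stratification boundaries follow the 0.3/0.7 rule exactly", {
  v <- matrix(c(0.30, 0.70, 0.45, 0.0, 1.0, 0.299, 0.701, NA), 1L,
              dimnames = list("c1", paste0("s", 1:8)))
  tern <- stratify(beta_matrix(v, c(c1 = "A")))
  expect_equal(unname(tern$values[1, ]),
               c(0, 1, 0.5, 0, 1, 0, 1, NA))
  expect_error(stratify(beta_matrix(v, c(c1 = "A")), 0.7, 0.3), "t_low")
})

test_that("stratification is idempotent and closed over {0, 0.5, 1, NA}", {
  set.seed(11)
  v <- matrix(stats::runif(400), 20L,
              dimnames = list(paste0("c", 1:20), paste0("s", 1:20)))
  v[sample(length(v), 15L)] <- NA
  tern <- stratify(beta_matrix(v, stats::setNames(paste0("g", 1:20),
                                                  rownames(v))))
  expect_true(all(tern$values %in% c(0, 0.5, 1) | is.na(tern$values)))
  expect_equal(stratify(tern)$values, tern$values)
})

test_that("methylation frequency counts hypermethylated calls per sample", {
  v <- matrix(c(1, 1, 0, 0.5,
                0, 0, 0, 0,
                1, NA, 0, 1), ncol = 3L,
              dimnames = list(paste0("c", 1:4), paste0("s", 1:3)))
  tern <- ternary_matrix(v, stats::setNames(paste0("g", 1:4), rownames(v)))
  freq <- methylation_frequency(tern)
  expect_equal(freq$methylation_frequency, c(0.5, 0, 2 / 3))
  expect_equal(freq$n_informative, c(4L, 4L, 3L))
  # subset restriction and its error contract
  expect_equal(methylation_frequency(tern, c("c1", "c2"))[[2]],
               c(1, 0, 1))
  expect_error(methylation_frequency(tern, character(0)), "non-empty")
  expect_error(methylation_frequency(tern, "nope"), "unknown CpG")
})

test_that("frequency is invariant under row and column permutation", {
  set.seed(21)
  v <- matrix(sample(c(0, 0.5, 1), 60L, replace = TRUE), 10L,
              dimnames = list(paste0("c", 1:10), paste0("s", 1:6)))
  tern <- ternary_matrix(v, stats::setNames(paste0("g", 1:10), rownames(v)))
  f0 <- methylation_frequency(tern)
  perm <- tern
  perm$values <- perm$values[sample(10L), sample(6L)]
  perm$gene <- perm$gene[rownames(perm$values)]
  f1 <- methylation_frequency(perm)
  expect_equal(f1$methylation_frequency[match(f0$sample_id, f1$sample_id)],
               f0$methylation_frequency)
})

test_that("centring subtracts the centring-set mean from every sample", {
  v <- matrix(c(1, 0, 0.5, 0.5,
                0.5, 0.5, 0.5, 0.5), 2L, byrow = TRUE,
              dimnames = list(c("c1", "c2"), paste0("s", 1:4)))
  tern <- ternary_matrix(v, c(c1 = "A", c2 = "B"))
  rel <- centre(tern)
  expect_equal(unname(rel$values["c1", ]), c(0.5, -0.5, 0, 0))
  expect_equal(unname(rel$values["c2", ]), rep(0, 4L))
  expect_equal(rowMeans(rel$values), c(c1 = 0, c2 = 0), tolerance = 1e-9)

  # samples outside the centring set are centred with the same mean
  rel2 <- centre(tern, centring_samples = c("s1", "s2"))
  expect_equal(unname(rel2$values["c1", ]), c(0.5, -0.5, 0, 0))

  # CpG with no informative centring value becomes all-missing
  v[1L, ] <- NA
  expect_warning(rel3 <- centre(ternary_matrix(v, c(c1 = "A", c2 = "B"))),
                 "no informative")
  expect_true(all(is.na(rel3$values["c1", ])))
})

test_that("the variability filter keeps CpGs with sample SD >= threshold", {
  v <- matrix(c(0, 1, 0, 1,
                0.5, 0.5, 0.5, 0.5,
                0, 0.5, 0, 0.5), 3L, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:4)))
  tern <- ternary_matrix(v, stats::setNames(paste0("g", 1:3), rownames(v)))
  rel <- centre(tern)
  kept <- filter_variable(rel, sd_min = 0.3)
  # sd of (0,1,0,1) is 0.577; the constant row and the 0/0.5 row (sd 0.289)
  # fall below 0.3
  expect_identical(rownames(kept$values), "c1")
  expect_equal(stats::sd(v[1L, ]), sqrt(1 / 3), tolerance = 1e-12)
})

test_that("centring does not change which CpGs pass the SD filter", {
  set.seed(31)
  v <- matrix(sample(c(0, 0.5, 1), 300L, replace = TRUE,
                     prob = c(0.5, 0.2, 0.3)), 30L,
              dimnames = list(paste0("c", 1:30), paste0("s", 1:10)))
  tern <- ternary_matrix(v, stats::setNames(paste0("g", 1:30), rownames(v)))
  expect_identical(rownames(filter_variable(tern)$values),
                   rownames(filter_variable(centre(tern))$values))
})

test_that("group mean frequencies track the planted methylation states", {
  cfg <- simulation_config(
    n_cpgs = 200L, n_genes = 100L,
    subtype_sizes = c("lumA" = 15L, "lumB" = 15L),
    baseline_meth = c("lumA" = 0.25, "lumB" = 0.40),
    n_normal = 0L, n_differential = 0L, n_marker_genes = 10L,
    genesets = list(), seed = 77)
  sim <- simulate_study(cfg)
  freq <- methylation_frequency(stratify(sim$beta))
  # independent oracle: Monte Carlo estimate of P(beta >= 0.7 | state) from
  # the channel model, weighted by the recorded truth states
  set.seed(991)
  p_hi <- vapply(1:3, function(st) {
    m <- stats::rlnorm(2e5, cfg$channel_meanlog[st, 1], cfg$channel_sdlog)
    u <- stats::rlnorm(2e5, cfg$channel_meanlog[st, 2], cfg$channel_sdlog)
    mean(m / (m + u) >= 0.7)
  }, numeric(1))
  for (g in c("lumA", "lumB")) {
    expected <- mean(p_hi[sim$truth$states[, g]])
    in_group <- sim$truth$sample_subtype[freq$sample_id] == g
    expect_equal(mean(freq$methylation_frequency[in_group]), expected,
                 tolerance = 0.02)
  }
})
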