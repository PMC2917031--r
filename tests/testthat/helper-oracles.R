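# Independent brute-force oracles used to validate the pipeline's
# implementations. Each oracle recomputes a quantity from first principles
# and must stay free of the code path it checks.

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the point probabilities of every table with the same margins whose
# probability does not exceed the observed one (with the same relative
# tolerance stats::fisher.test uses).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  obs <- probs[x == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sided exact binomial p at p0 = 0.5 by direct summation of all
# outcome probabilities at most the observed one (minlike convention).
binom_p_oracle <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  obs <- probs[k + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pearson distance from the covariance/SD definition (no cor()).
pearson_distance_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cov_xy <- sum((x - mx) * (y - my)) / (n - 1)
  1 - cov_xy / (sqrt(sum((x - mx)^2) / (n - 1)) *
                  sqrt(sum((y - my)^2) / (n - 1)))
}

# O(n^3) UPGMA on a distance matrix: at every step recompute every
# between-cluster average over the ORIGINAL pairwise distances, merge the
# closest pair. Returns merge heights and the partition after each merge
# (as a list of sample-id sets).
upgma_oracle <- function(d) {
  ids <- rownames(d)
  clusters <- as.list(ids)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, function(z) sort(z))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (for label-free comparison): sorted list of
# sorted member vectors
canonical_partition <- function(members_by_cluster) {
  parts <- lapply(unname(members_by_cluster), function(z)
    sort(as.character(z)))
  parts[order(vapply(parts, `[`, character(1L), 1L))]
}

# one-way ANOVA F by the direct sum-of-squares formula, one vector
f_stat_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(z)
    length(z) * (mean(z) - grand)^2))
  ssw <- sum(tapply(values, groups, function(z) sum((z - mean(z))^2)))
  (ssb / (nlevels(groups) - 1)) / (ssw / (length(values) - nlevels(groups)))
}

# SAM components by the direct Tusher formulas, one vector
sam_d_oracle <- function(values, in_mask, s0) {
  x <- values[in_mask]
  y <- values[!in_mask]
  n1 <- length(x)
  n2 <- length(y)
  s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) *
              (sum((x - mean(x))^2) + sum((y - mean(y))^2)))
  (mean(x) - mean(y)) / (s + s0)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# deterministic small relative matrix for clustering/differential tests
random_relative <- function(n_cpgs, n_samples, seed,
                            genes_per_cpg = NULL) {
  set.seed(seed)
  v <- matrix(stats::runif(n_cpgs * n_samples, -1, 1), n_cpgs,
              dimnames = list(paste0("c", seq_len(n_cpgs)),
                              paste0("s", seq_len(n_samples))))
  gene <- if (is.null(genes_per_cpg))
    paste0("g", seq_len(n_cpgs)) else genes_per_cpg
  relative_matrix(v, stats::setNames(gene, rownames(v)))
}
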