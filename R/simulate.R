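#' Configuration for the synthetic methylation study generator
#'
#' Assembles and validates the parameters of [simulate_study]. The defaults
#' emulate a GoldenGate-style breast-tumour methylation study: five molecular
#' subtypes at realistic sizes plus a few normal-tissue samples, bimodal
#' beta-values arising as M/(M+U) from two lognormal channel intensities, a
#' per-subtype baseline methylation probability ordered lumB > lumA > basal,
#' planted subtype-differential CpGs, methylation-coupled (anti-correlated)
#' expression for a configurable fraction of genes, subtype expression
#' markers that define centroids, and gene sets with planted methylation
#' shifts.
#'
#' @param n_cpgs number of CpG sites.
#' @param n_genes number of genes; each CpG belongs to exactly one gene.
#' @param cpgs_per_gene probabilities that a gene carries 1, 2, 3, ... CpGs.
#' @param subtype_sizes named integer vector of tumour counts per subtype.
#' @param n_normal number of normal-tissue samples.
#' @param baseline_meth named per-subtype probability that a CpG is
#'   constitutively methylated in that subtype.
#' @param normal_tissue_meth same probability for normal tissue.
#' @param variable_prob probability mass of the hemimethylated (variable)
#'   latent state, shared by all groups.
#' @param n_differential number of planted subtype-differential CpGs.
#' @param differential_effect planted effect on the stratified (ternary)
#'   scale; the target subtype's latent state is the one whose expected
#'   stratified value is nearest to the other subtypes' value +/- this effect.
#' @param n_marker_genes number of genes given subtype-specific expression
#'   (cycled over the subtypes); these define the centroid table.
#' @param marker_effect expression shift of a marker gene in its subtype.
#' @param coupling_fraction fraction of genes whose expression is
#'   anti-correlated with their methylation.
#' @param coupling_strength multiplier of the (centred) methylation signal
#'   subtracted from a coupled gene's expression.
#' @param expression_noise_sd SD of the additive expression noise.
#' @param two_probe_fraction fraction of genes measured by two probes.
#' @param channel_meanlog 3x2 matrix of lognormal meanlog parameters for the
#'   methylated (M) and unmethylated (U) channel, one row per latent state
#'   (unmethylated, variable, methylated).
#' @param channel_sdlog lognormal sdlog for both channels.
#' @param missing_rate fraction of beta cells set missing.
#' @param genesets list of planted gene sets, each
#'   `list(name =, n_genes =, subtype = or NULL, shift =)`; a shifted set
#'   raises its genes' methylation probability by `shift` in `subtype`.
#' @param seed mandatory integer master seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_cpgs = 500L,
    n_genes = 250L,
    cpgs_per_gene = c(0.6, 0.3, 0.1),
    subtype_sizes = c("basal-like" = 43L, "lumA" = 46L, "lumB" = 35L,
                      "HER2-enriched" = 14L, "normal-like" = 17L),
    n_normal = 4L,
    baseline_meth = c("basal-like" = 0.276, "lumA" = 0.311, "lumB" = 0.351,
                      "HER2-enriched" = 0.278, "normal-like" = 0.275),
    normal_tissue_meth = 0.273,
    variable_prob = 0.2,
    n_differential = 50L,
    differential_effect = 0.4,
    n_marker_genes = 50L,
    marker_effect = 1.5,
    coupling_fraction = 0.44,
    coupling_strength = 1.5,
    expression_noise_sd = 0.5,
    two_probe_fraction = 0.15,
    channel_meanlog = rbind(unmethylated = c(log(0.12), log(1)),
                            variable = c(log(0.5), log(0.5)),
                            methylated = c(log(1), log(0.12))),
    channel_sdlog = 0.3,
    missing_rate = 0,
    genesets = list(
      list(name = "PRC2_TARGETS_SYNTH", n_genes = 40L, subtype = "lumB",
           shift = 0.3),
      list(name = "DECOY_SET_SYNTH", n_genes = 40L, subtype = NULL,
           shift = 0)),
    seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_cpgs >= 1L, n_genes >= 1L, n_cpgs >= n_genes,
            all(subtype_sizes > 0L), n_normal >= 0L,
            all(baseline_meth >= 0 & baseline_meth <= 1),
            normal_tissue_meth >= 0, normal_tissue_meth <= 1,
            variable_prob >= 0, variable_prob <= 1,
            n_differential >= 0L, differential_effect >= 0,
            coupling_fraction >= 0, coupling_fraction <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_differential > n_cpgs)
    stop("more differential CpGs than CpGs", call. = FALSE)
  if (!setequal(names(subtype_sizes), names(baseline_meth)))
    stop("'subtype_sizes' and 'baseline_meth' must name the same subtypes",
         call. = FALSE)
  if (any(baseline_meth + variable_prob > 1))
    stop("baseline_meth + variable_prob exceeds 1", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

# expected stratified value of each latent state under the channel model
state_expected_values <- function(cfg) {
  sdr <- sqrt(2) * cfg$channel_sdlog
  vapply(1:3, function(st) {
    mu <- cfg$channel_meanlog[st, 1L] - cfg$channel_meanlog[st, 2L]
    # beta >= t  <=>  log(M/U) >= log(t/(1-t))
    p_hi <- stats::pnorm(log(0.7 / 0.3), mu, sdr, lower.tail = FALSE)
    p_lo <- stats::pnorm(log(0.3 / 0.7), mu, sdr)
    p_hi + 0.5 * (1 - p_hi - p_lo)
  }, numeric(1L))
}

#' Simulate a methylation study with known ground truth
#'
#' Generates the full fixture bundle the pipeline consumes: a beta-value
#' matrix, a probe-level expression matrix (tumour samples only), a sample
#' annotation table, gene sets, a subtype centroid table, and a truth record
#' for every planted effect. One random stream per output matrix is split
#' from the master seed, so enlarging one output does not perturb the others.
#'
#' Latent states are coupled across groups by a common uniform draw per CpG:
#' a group with higher methylation probability is methylated at a superset of
#' the CpGs of a group with lower probability. Consequently a configuration
#' with equal probabilities across subtypes is exactly null per CpG.
#'
#' @param config a [simulation_config].
#' @return A list with elements `beta` ([beta_matrix]), `expression`
#'   ([expression_matrix]), `annotation` (data.frame), `genesets` (named
#'   list), `centroids` (gene x subtype matrix) and `truth` (see Details).
#'   `truth` records `sample_subtype`, the latent `states` (CpG x group,
#'   1 = unmethylated, 2 = variable, 3 = methylated), `expected_strat`
#'   (expected stratified value per CpG and group), `p_meth` (the per-CpG
#'   per-group methylation probabilities after planted shifts),
#'   `differential` (data.frame of planted CpGs with target subtype and
#'   sign), `coupled_genes`, `marker_genes` (named by subtype) and
#'   `geneset_members`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  stream <- sample.int(.Machine$integer.max - 1L, 6L)

  subtypes <- names(cfg$subtype_sizes)
  groups <- c(subtypes, if (cfg$n_normal > 0L) "normal")

  ## -- structure stream: gene map, planted effects ------------------------
  set.seed(stream[1L])
  counts <- sample(seq_along(cfg$cpgs_per_gene), cfg$n_genes, replace = TRUE,
                   prob = cfg$cpgs_per_gene)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  cpg_gene <- rep(gene_ids, counts)
  # pad or trim to exactly n_cpgs, keeping every gene represented
  if (length(cpg_gene) < cfg$n_cpgs)
    cpg_gene <- c(cpg_gene, sample(gene_ids, cfg$n_cpgs - length(cpg_gene),
                                   replace = TRUE))
  cpg_gene <- cpg_gene[seq_len(cfg$n_cpgs)]
  if (!all(gene_ids %in% cpg_gene))  # trim may have dropped late genes
    gene_ids <- unique(cpg_gene)
  cpg_ids <- paste0(cpg_gene, "_P",
                    stats::ave(seq_along(cpg_gene), cpg_gene,
                               FUN = seq_along), "_F")
  names(cpg_gene) <- cpg_ids

  geneset_members <- list()
  available <- gene_ids
  for (gs in cfg$genesets) {
    take <- sample(available, min(gs$n_genes, length(available)))
    geneset_members[[gs$name]] <- take
    available <- setdiff(available, take)
  }
  marker_genes <- sample(available, min(cfg$n_marker_genes,
                                        length(available)))
  marker_subtype <- stats::setNames(
    rep(subtypes, length.out = length(marker_genes)), marker_genes)
  coupled_genes <- sample(gene_ids,
                          round(cfg$coupling_fraction * length(gene_ids)))

  # per-CpG per-group methylation probability
  p_meth <- matrix(rep(c(cfg$baseline_meth,
                         if (cfg$n_normal > 0L) cfg$normal_tissue_meth),
                       each = cfg$n_cpgs),
                   nrow = cfg$n_cpgs, dimnames = list(cpg_ids, groups))
  for (gs in cfg$genesets) {
    if (is.null(gs$subtype) || gs$shift == 0) next
    rows <- cpg_gene %in% geneset_members[[gs$name]]
    p_meth[rows, gs$subtype] <- pmin(
      p_meth[rows, gs$subtype] + gs$shift, 1 - cfg$variable_prob)
  }

  # latent states via a common uniform per CpG (comonotone across groups)
  u <- stats::runif(cfg$n_cpgs)
  states <- matrix(1L, cfg$n_cpgs, length(groups),
                   dimnames = list(cpg_ids, groups))
  for (g in groups) {
    states[u < p_meth[, g] + cfg$variable_prob, g] <- 2L
    states[u < p_meth[, g], g] <- 3L
  }

  # planted differential CpGs: nearest-state override for a target subtype
  ev <- state_expected_values(cfg)
  nondiff_pool <- setdiff(cpg_ids, cpg_ids[cpg_gene %in%
                                             unlist(geneset_members)])
  diff_cpgs <- sample(nondiff_pool, min(cfg$n_differential,
                                        length(nondiff_pool)))
  differential <- data.frame(cpg_id = character(), target = character(),
                             sign = integer(), stringsAsFactors = FALSE)
  if (length(diff_cpgs)) {
    target <- rep(subtypes, length.out = length(diff_cpgs))
    pref <- rep(c(1L, -1L), length.out = length(diff_cpgs))
    sgn <- integer(length(diff_cpgs))
    for (i in seq_along(diff_cpgs)) {
      cpg <- diff_cpgs[i]
      others <- setdiff(subtypes, target[i])
      e_others <- mean(ev[states[cpg, others]])
      # a shift that clamps at 0 or 1 plants no effect; pick the direction
      # that realises the larger one, preferring the alternating sign on ties
      nearest <- function(s) {
        wanted <- min(max(e_others + s * cfg$differential_effect, 0), 1)
        which.min(abs(ev - wanted))
      }
      st <- vapply(c(pref[i], -pref[i]), nearest, integer(1L))
      gain <- abs(ev[st] - e_others)
      use <- if (gain[2L] > gain[1L]) 2L else 1L
      sgn[i] <- c(pref[i], -pref[i])[use]
      states[cpg, target[i]] <- st[use]
    }
    differential <- data.frame(cpg_id = diff_cpgs, target = target,
                               sign = sgn, stringsAsFactors = FALSE)
  }

  ## -- sample layout ------------------------------------------------------
  sample_group <- rep(groups, times = c(cfg$subtype_sizes,
                                        if (cfg$n_normal > 0L) cfg$n_normal))
  sample_ids <- c(sprintf("T%03d", seq_len(sum(cfg$subtype_sizes))),
                  if (cfg$n_normal > 0L) sprintf("N%02d",
                                                 seq_len(cfg$n_normal)))
  names(sample_group) <- sample_ids

  ## -- beta stream --------------------------------------------------------
  set.seed(stream[2L])
  st_cell <- states[, sample_group, drop = FALSE]
  m_chan <- stats::rlnorm(length(st_cell),
                          cfg$channel_meanlog[st_cell, 1L],
                          cfg$channel_sdlog)
  u_chan <- stats::rlnorm(length(st_cell),
                          cfg$channel_meanlog[st_cell, 2L],
                          cfg$channel_sdlog)
  beta_vals <- matrix(m_chan / (m_chan + u_chan), cfg$n_cpgs,
                      length(sample_ids),
                      dimnames = list(cpg_ids, sample_ids))
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(beta_vals)) < cfg$missing_rate
    beta_vals[drop] <- NA_real_
  }
  beta <- beta_matrix(beta_vals, cpg_gene)

  ## -- expression stream (tumour samples only) ----------------------------
  set.seed(stream[3L])
  tumour_ids <- sample_ids[sample_group != "normal"]
  tern <- stratify(beta)
  gene_meth <- collapse_cpgs_to_genes(tern$values[, tumour_ids,
                                                  drop = FALSE], cpg_gene)
  expr_gene <- matrix(0, length(gene_ids), length(tumour_ids),
                      dimnames = list(gene_ids, tumour_ids))
  for (g in names(marker_subtype))
    expr_gene[g, sample_group[tumour_ids] == marker_subtype[g]] <-
      cfg$marker_effect
  for (g in coupled_genes) {
    mg <- gene_meth[g, ]
    expr_gene[g, ] <- expr_gene[g, ] -
      cfg$coupling_strength * (mg - mean(mg, na.rm = TRUE))
  }
  expr_gene <- expr_gene + matrix(
    stats::rnorm(length(expr_gene), 0, cfg$expression_noise_sd),
    nrow(expr_gene))
  # probe layer: every gene one probe; a fraction gets a noisier second probe
  two_probe <- sample(gene_ids,
                      round(cfg$two_probe_fraction * length(gene_ids)))
  probe_gene <- c(gene_ids, two_probe)
  probe_ids <- c(paste0("PR_", gene_ids, "_1"), paste0("PR_", two_probe,
                                                       "_2"))
  expr_vals <- rbind(expr_gene,
                     expr_gene[two_probe, , drop = FALSE] + matrix(
                       stats::rnorm(length(two_probe) * length(tumour_ids),
                                    0, cfg$expression_noise_sd / 2),
                       length(two_probe)))
  rownames(expr_vals) <- probe_ids
  # centre across tumour samples: relative expression levels
  expr_vals <- expr_vals - rowMeans(expr_vals, na.rm = TRUE)
  expression <- expression_matrix(expr_vals,
                                  stats::setNames(probe_gene, probe_ids))

  ## -- centroids: per-subtype mean expression of marker genes -------------
  gv <- collapse_probes(expression, "mean")
  centroids <- vapply(subtypes, function(st) {
    rowMeans(gv[marker_genes, sample_group[tumour_ids] == st,
                drop = FALSE], na.rm = TRUE)
  }, numeric(length(marker_genes)))
  rownames(centroids) <- marker_genes

  ## -- annotation stream --------------------------------------------------
  set.seed(stream[4L])
  annotation <- simulate_annotation(sample_ids, sample_group, subtypes)

  truth <- list(sample_subtype = sample_group,
                states = states,
                expected_strat = matrix(ev[states], nrow(states),
                                        ncol(states),
                                        dimnames = dimnames(states)),
                p_meth = p_meth,
                differential = differential,
                coupled_genes = coupled_genes,
                marker_genes = marker_subtype,
                geneset_members = geneset_members,
                state_values = ev)

  list(beta = beta, expression = expression, annotation = annotation,
       genesets = geneset_members, centroids = centroids, truth = truth)
}

# mean stratified value per gene over its CpGs (gene x sample)
collapse_cpgs_to_genes <- function(values, cpg_gene) {
  genes <- unique(cpg_gene)
  out <- matrix(NA_real_, length(genes), ncol(values),
                dimnames = list(genes, colnames(values)))
  for (g in genes)
    out[g, ] <- colMeans(values[cpg_gene == g, , drop = FALSE], na.rm = TRUE)
  out
}

# clinical covariates with subtype-dependent hormone-receptor rates
simulate_annotation <- function(sample_ids, sample_group, subtypes) {
  er_pos <- c("basal-like" = 0.05, "lumA" = 0.96, "lumB" = 0.91,
              "HER2-enriched" = 0.36, "normal-like" = 0.67)
  pgr_pos <- c("basal-like" = 0.05, "lumA" = 0.96, "lumB" = 0.82,
               "HER2-enriched" = 0.36, "normal-like" = 0.53)
  n <- length(sample_ids)
  is_tumour <- sample_group != "normal"
  subtype <- ifelse(is_tumour, sample_group, "non-GEX")
  p_er <- ifelse(is_tumour, er_pos[sample_group], 0.5)
  p_pgr <- ifelse(is_tumour, pgr_pos[sample_group], 0.5)
  p_er[is.na(p_er)] <- 0.5    # custom subtype names beyond the defaults
  p_pgr[is.na(p_pgr)] <- 0.5
  data.frame(
    sample_id = sample_ids,
    subtype = subtype,
    er_status = ifelse(stats::runif(n) < p_er, "positive", "negative"),
    pgr_status = ifelse(stats::runif(n) < p_pgr, "positive", "negative"),
    family_status = sample(c("BRCA1", "BRCA2", "familial", "sporadic"), n,
                           replace = TRUE,
                           prob = c(0.08, 0.07, 0.23, 0.62)),
    grade = sample(c("1", "2", "3"), n, replace = TRUE,
                   prob = c(0.12, 0.32, 0.56)),
    node_status = sample(c("positive", "negative"), n, replace = TRUE,
                         prob = c(0.3, 0.7)),
    age = round(stats::rnorm(n, 48, 8)),
    size_mm = round(stats::rlnorm(n, log(20), 0.4)),
    tissue = ifelse(is_tumour, "tumour", "normal"),
    stringsAsFactors = FALSE)
}

#' A tiny hand-checkable fixture
#'
#' A fixed 8-CpG by 6-sample bundle with literal values, including one CpG
#' carrying each stratification boundary case (0.30, 0.45, 0.70). Samples
#' s1-s5 are tumours (two basal-like, two lumA, one lumB); s6 is normal
#' tissue. Four genes with two CpGs each; the four-probe expression matrix
#' covers the five tumours, with probe PR_g1 anti-correlated with gene g1's
#' methylation.
#'
#' @return A list with `beta`, `expression`, `annotation` and `geneset`.
#' @export
worked_fixture <- function() {
  cpg_ids <- paste0("c", 1:8)
  samples <- paste0("s", 1:6)
  gene <- stats::setNames(rep(paste0("g", 1:4), each = 2L), cpg_ids)
  beta_vals <- matrix(c(
    0.30, 0.80, 0.90, 0.85, 0.75, 0.10,  # c1: boundary 0.30 in s1
    0.45, 0.70, 0.80, 0.90, 0.85, 0.05,  # c2: boundary 0.45, 0.70
    0.10, 0.15, 0.20, 0.05, 0.10, 0.10,  # c3: constitutively unmethylated
    0.95, 0.90, 0.85, 0.90, 0.95, 0.20,  # c4: constitutively methylated
    0.20, 0.25, 0.75, 0.80, 0.85, 0.15,  # c5: lumA/lumB methylated
    0.10, 0.20, 0.80, 0.75, 0.90, 0.10,  # c6: lumA/lumB methylated
    0.50, 0.55, 0.45, 0.40, 0.60, 0.50,  # c7: hemimethylated throughout
    0.05, 0.95, 0.50, 0.10, 0.90, 0.05   # c8: mixed
  ), nrow = 8L, byrow = TRUE, dimnames = list(cpg_ids, samples))
  tumours <- samples[1:5]
  expr_vals <- matrix(c(
    1.2, -0.8, -1.0, -0.9, -0.7,   # PR_g1: anti-correlated with c1/c2
    0.1, 0.0, -0.1, 0.2, -0.2,     # PR_g2: flat
    1.0, 0.9, -0.8, -1.1, -0.9,    # PR_g3: anti-correlated with c5/c6
    0.3, -0.4, 0.1, 0.0, 0.2       # PR_g4: unrelated
  ), nrow = 4L, byrow = TRUE,
  dimnames = list(paste0("PR_g", 1:4), tumours))
  annotation <- data.frame(
    sample_id = samples,
    subtype = c("basal-like", "basal-like", "lumA", "lumA", "lumB",
                "non-GEX"),
    er_status = c("negative", "negative", "positive", "positive",
                  "positive", "unknown"),
    pgr_status = c("negative", "negative", "positive", "positive",
                   "positive", "unknown"),
    family_status = c("sporadic", "BRCA1", "sporadic", "familial",
                      "BRCA2", "sporadic"),
    grade = c("3", "3", "1", "2", "3", NA),
    node_status = c("negative", "positive", "negative", "negative",
                    "positive", NA),
    age = c(45, 39, 52, 60, 48, 55),
    size_mm = c(22, 30, 15, 18, 25, NA),
    tissue = c(rep("tumour", 5L), "normal"),
    stringsAsFactors = FALSE)
  list(beta = beta_matrix(beta_vals, gene),
       expression = expression_matrix(
         expr_vals, stats::setNames(paste0("g", 1:4),
                                    paste0("PR_g", 1:4))),
       annotation = annotation,
       geneset = list(FIXTURE_SET = c("g1", "g3")))
}
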