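#' Average relative methylation and expression of a gene set per sample
#'
#' The methylation score of a sample is the unweighted mean of the relative
#' methylation levels of all CpG sites whose gene symbol belongs to the set
#' (CpG-level averaging: genes with more CpG sites weigh more). The expression
#' score is the mean over matched genes after collapsing probes per gene.
#' Either matrix may be omitted.
#'
#' @param rel a [relative_matrix], or `NULL`.
#' @param expr an [expression_matrix], or `NULL`.
#' @param geneset character vector of gene symbols.
#' @param set_name label written into the result (default
#'   the deparsed argument).
#' @return A data.frame with one row per sample: `sample_id`, `set_name`,
#'   `avg_rel_methylation`, `avg_rel_expression`, `n_cpgs_matched`,
#'   `n_genes_matched`. Scores are `NA` where nothing matched.
#' @export
score_geneset <- function(rel = NULL, expr = NULL, geneset,
                          set_name = "geneset") {
  if (length(geneset) == 0L) stop("empty gene set", call. = FALSE)
  symbols <- norm_symbol(geneset)
  samples <- unique(c(if (!is.null(rel)) colnames(rel$values),
                      if (!is.null(expr)) colnames(expr$values)))
  meth <- rep(NA_real_, length(samples))
  expn <- rep(NA_real_, length(samples))
  n_cpgs <- 0L
  n_genes <- 0L
  if (!is.null(rel)) {
    hit <- norm_symbol(rel$gene) %in% symbols
    n_cpgs <- sum(hit)
    if (n_cpgs > 0L) {
      sc <- colMeans(rel$values[hit, , drop = FALSE], na.rm = TRUE)
      meth[match(names(sc), samples)] <- sc
    }
  }
  if (!is.null(expr)) {
    gv <- collapse_probes(expr, "mean")
    hit <- rownames(gv) %in% symbols
    n_genes <- sum(hit)
    if (n_genes > 0L) {
      sc <- colMeans(gv[hit, , drop = FALSE], na.rm = TRUE)
      expn[match(names(sc), samples)] <- sc
    }
  }
  if (n_cpgs == 0L && n_genes == 0L)
    stop("gene set '", set_name, "' matches no CpG site and no gene",
         call. = FALSE)
  data.frame(sample_id = samples, set_name = set_name,
             avg_rel_methylation = ifelse(is.nan(meth), NA, meth),
             avg_rel_expression = ifelse(is.nan(expn), NA, expn),
             n_cpgs_matched = n_cpgs, n_genes_matched = n_genes,
             stringsAsFactors = FALSE)
}

#' Compare gene-set scores between sample groups
#'
#' Contrasts per-sample gene-set scores (methylation or expression) across an
#' annotation field, by one-way ANOVA over all levels or a two-sample t-test
#' between two named levels. Samples with missing scores are excluded with a
#' logged count.
#'
#' @param scores data.frame from [score_geneset] (several sets may be
#'   row-bound).
#' @param annotation data.frame as from [read_annotation].
#' @param value which score to contrast: `"methylation"` or `"expression"`.
#' @param test `"anova"` (all levels) or `"t"` (two levels).
#' @param field annotation column defining the groups (default `"subtype"`).
#' @param levels for `test = "t"`, the two levels to compare; for
#'   `test = "anova"`, optional restriction of the levels used. Levels in
#'   `drop_levels` are always excluded.
#' @param drop_levels levels excluded entirely (default non-classified,
#'   non-GEX, unknown).
#' @return A data.frame, one row per gene set: group means, `statistic`,
#'   `p_value`.
#' @export
contrast_geneset <- function(scores, annotation,
                             value = c("methylation", "expression"),
                             test = c("anova", "t"), field = "subtype",
                             levels = NULL,
                             drop_levels = c("non-classified", "non-GEX",
                                             "unknown")) {
  value <- match.arg(value)
  test <- match.arg(test)
  col <- if (value == "methylation") "avg_rel_methylation"
         else "avg_rel_expression"
  ann <- annotation[match(scores$sample_id, annotation$sample_id), ,
                    drop = FALSE]
  grp <- ann[[field]]
  keep <- !is.na(grp) & !(grp %in% drop_levels) & !is.na(scores[[col]])
  if (!is.null(levels)) keep <- keep & grp %in% levels
  n_dropped <- sum(is.na(scores[[col]]))
  if (n_dropped > 0L)
    message(n_dropped, " sample(s) with missing scores excluded")
  sc <- scores[keep, , drop = FALSE]
  grp <- grp[keep]
  out <- lapply(unique(sc$set_name), function(nm) {
    sel <- sc$set_name == nm
    x <- sc[[col]][sel]
    g <- grp[sel]
    if (test == "t" && length(unique(g)) != 2L)
      stop("t contrast needs exactly 2 levels; give 'levels'", call. = FALSE)
    cmp <- group_compare(x, g, test = test)
    means <- tapply(x, g, mean)
    cbind(data.frame(set_name = nm, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            means, paste0("mean_", names(means)))), check.names = FALSE),
          data.frame(statistic = cmp$statistic, p_value = cmp$p_value,
                     test = test))
  })
  do.call(rbind, out)
}

#' Compare gene-set CpGs against all other CpGs within a sample group
#'
#' Within the given sample subset, every CpG's mean relative methylation is
#' computed; a two-sample t-test then compares the CpGs matching the gene set
#' against all remaining CpGs (is the set more methylated than the rest of
#' the panel in these samples?).
#'
#' @param rel a [relative_matrix].
#' @param geneset character vector of gene symbols.
#' @param samples character vector of sample ids defining the group
#'   (default all samples).
#' @param var_equal passed to [group_compare] (default `FALSE`, Welch).
#' @return A list with `mean_in_set`, `mean_other_genes`, `n_cpgs_in_set`,
#'   `n_cpgs_other`, `statistic` (t) and `p_value`.
#' @export
compare_set_vs_rest <- function(rel, geneset, samples = colnames(rel$values),
                                var_equal = FALSE) {
  missing_ids <- setdiff(samples, colnames(rel$values))
  if (length(missing_ids))
    stop("unknown sample id: ", missing_ids[1L], call. = FALSE)
  hit <- norm_symbol(rel$gene) %in% norm_symbol(geneset)
  if (!any(hit)) stop("gene set matches no CpG site", call. = FALSE)
  if (all(hit)) stop("gene set matches every CpG site; empty complement",
                     call. = FALSE)
  per_cpg <- rowMeans(rel$values[, samples, drop = FALSE], na.rm = TRUE)
  cmp <- group_compare(per_cpg, ifelse(hit, "in_set", "other"), test = "t",
                       var_equal = var_equal)
  list(mean_in_set = mean(per_cpg[hit], na.rm = TRUE),
       mean_other_genes = mean(per_cpg[!hit], na.rm = TRUE),
       n_cpgs_in_set = sum(hit), n_cpgs_other = sum(!hit),
       statistic = cmp$statistic, p_value = cmp$p_value)
}
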