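#' Read a CpG beta-value matrix
#'
#' Reads a tab-delimited table whose first column holds CpG site ids, one
#' column holds gene symbols, and the remaining columns hold beta-values in
#' \[0,1\] (one column per sample). Empty cells become missing values. The
#' dialect mirrors deposited GoldenGate methylation tables: one row per CpG
#' site, a gene annotation column, and sample columns in deposition order.
#'
#' @param path path to a tab-delimited text file.
#' @param gene_column name of the gene-symbol annotation column
#'   (default `"gene"`).
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path, gene_column = "gene") {
  read_feature_matrix(path, gene_column, beta_matrix, range = c(0, 1))
}

#' Read a probe-level relative expression matrix
#'
#' Same dialect as [read_beta_matrix]: first column probe ids, one gene-symbol
#' column, remaining columns numeric relative expression (centred log scale,
#' unbounded).
#'
#' @inheritParams read_beta_matrix
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, gene_column = "gene") {
  read_feature_matrix(path, gene_column, expression_matrix, range = NULL)
}

read_feature_matrix <- function(path, gene_column, constructor, range) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  if (!gene_column %in% names(df))
    stop("gene column '", gene_column, "' not found in ", path, call. = FALSE)
  gene <- df[[gene_column]]
  sample_cols <- setdiff(names(df)[-1L], gene_column)
  if (anyDuplicated(sample_cols))
    stop("sample ids not unique in ", path, call. = FALSE)
  values <- matrix(NA_real_, nrow(df), length(sample_cols),
                   dimnames = list(ids, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- trimws(df[[sample_cols[j]]])
    empty <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' at row '", ids[bad[1L]],
           "', column '", sample_cols[j], "' in ", path, call. = FALSE)
    if (!is.null(range)) {
      out_of_range <- which(!is.na(num) & (num < range[1L] | num > range[2L]))
      if (length(out_of_range))
        stop("value ", num[out_of_range[1L]], " outside [", range[1L], ", ",
             range[2L], "] at row '", ids[out_of_range[1L]], "', column '",
             sample_cols[j], "' in ", path, call. = FALSE)
    }
    values[, j] <- num
  }
  constructor(values, stats::setNames(gene, ids))
}

#' Write a feature-by-sample matrix container to tab-delimited text
#'
#' Writes the container in the dialect [read_beta_matrix] reads back: feature
#' id column, gene column, then sample columns. Full precision, "."-decimal,
#' missing values as empty cells. `write_beta_matrix` also serves ternary and
#' relative matrices.
#'
#' @param x a [beta_matrix], [ternary_matrix], [relative_matrix] or
#'   [expression_matrix].
#' @param path output file path.
#' @param gene_column name written for the gene-symbol column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, gene_column = "gene") {
  v <- format(x$values, digits = 15, trim = TRUE, scientific = FALSE)
  v[is.na(x$values)] <- ""
  df <- data.frame(id = rownames(x$values), gene = unname(x$gene), v,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("cpg_id", gene_column, colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
write_expression <- function(x, path, gene_column = "gene") {
  write_beta_matrix(x, path, gene_column)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-delimited fields
#' `name`, `description`, then gene symbols. Descriptions are discarded;
#' duplicated symbols within a line are removed with a warning.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of gene symbols, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    symbols <- fields[-(1:2)]
    symbols <- symbols[nzchar(trimws(symbols))]
    if (anyDuplicated(symbols)) {
      warning("duplicated symbols in gene set '", fields[1L],
              "' (line ", i, "); deduplicated", call. = FALSE)
      symbols <- unique(symbols)
    }
    nms[i] <- fields[1L]
    sets[[i]] <- symbols
  }
  stats::setNames(sets, nms)
}

#' @rdname read_gmt
#' @param genesets named list of character vectors.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], "na", genesets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

ANNOTATION_COLUMNS <- c("sample_id", "subtype", "er_status", "pgr_status",
                        "family_status", "grade", "node_status", "age",
                        "size_mm", "tissue")

#' Read a sample annotation table
#'
#' Tab-delimited table with a `sample_id` column and any subset of the
#' clinical columns `subtype`, `er_status`, `pgr_status`, `family_status`,
#' `grade`, `node_status`, `age`, `size_mm`, `tissue`. Subtype labels are
#' case-folded onto the closed vocabulary (basal-like, lumA, lumB,
#' HER2-enriched, normal-like, non-classified, non-GEX); unrecognised values
#' in other categorical columns become `"unknown"`.
#'
#' @param path path to a tab-delimited text file.
#' @return A data.frame, one row per sample.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("annotation must have a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("sample ids not unique: ",
         df$sample_id[duplicated(df$sample_id)][1L], call. = FALSE)
  if ("subtype" %in% names(df)) df$subtype <- normalise_subtype(df$subtype)
  for (col in intersect(c("er_status", "pgr_status"), names(df)))
    df[[col]] <- normalise_levels(df[[col]], c("positive", "negative"))
  if ("family_status" %in% names(df))
    df$family_status <- normalise_levels(
      df$family_status, c("BRCA1", "BRCA2", "familial", "sporadic"))
  if ("tissue" %in% names(df))
    df$tissue <- normalise_levels(df$tissue, c("tumour", "normal"),
                                  unknown = NA_character_)
  for (col in intersect(c("age", "size_mm"), names(df)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df
}

normalise_levels <- function(x, levels, unknown = "unknown") {
  idx <- match(tolower(trimws(x)), tolower(levels))
  out <- levels[idx]
  out[is.na(idx)] <- unknown
  out
}

#' @rdname read_annotation
#' @param annotation data.frame as returned by [read_annotation].
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-subtype centroid table
#'
#' Tab-delimited table: first column gene symbols, remaining columns one per
#' subtype centroid (relative expression values).
#'
#' @param path path to a tab-delimited text file.
#' @return A numeric matrix, genes in rows, subtype centroids in columns.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene in centroid table: ",
         genes[duplicated(genes)][1L], call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric centroid values in ", path,
                           call. = FALSE)
  if (anyNA(m)) stop("missing centroid values in ", path, call. = FALSE)
  rownames(m) <- genes
  m
}

#' @rdname read_centroids
#' @param centroids numeric gene-by-subtype matrix.
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(gene = rownames(centroids),
                   format(centroids, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", colnames(centroids))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
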