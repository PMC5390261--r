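#' Annotate proteins with functional categories
#'
#' Attaches exactly one category label per row, looked up by gene symbol
#' (falling back to accession when no `gene` column exists). Unmapped rows
#' receive `"Unknown function"`.
#'
#' @param table data.frame with a `gene` (or `accession`) column.
#' @param map data.frame with columns `gene` and `category` (first match
#'   wins for duplicated symbols).
#' @return `table` with a `category` column.
#' @export
assign_categories <- function(table, map) {
  key <- if (!is.null(table$gene)) table$gene else table$accession
  idx <- match(key, map$gene)
  table$category <- ifelse(is.na(idx), "Unknown function",
                           map$category[idx])
  table
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-category percentage distribution
#'
#' Counts rows per category and converts to percentages of `total`, rounded
#' half-up to one decimal (percentages are computed from unrounded
#' fractions). `total` defaults to the number of rows; it can be overridden
#' when the denominator of interest is a reported group size rather than the
#' table's own row count (for example when a published table carries
#' context rows beyond the reported selection).
#'
#' @param annotated data.frame with a `category` column; must be non-empty.
#' @param total denominator for the percentages.
#' @return data.frame with `category`, `count`, `percent`, sorted by
#'   decreasing count then category.
#' @export
category_distribution <- function(annotated, total = nrow(annotated)) {
  if (nrow(annotated) == 0)
    stop("cannot summarise an empty table", call. = FALSE)
  tab <- table(annotated$category)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$count / total, 1)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most extreme protein of a curated table
#'
#' Returns the row with the minimum Rsc (`direction = "down"`) or maximum
#' Rsc (`direction = "up"`); ties are broken lexicographically by gene
#' symbol. The result does not depend on row order.
#'
#' @param table non-empty data.frame with `gene` and `rsc` columns.
#' @param direction `"down"` or `"up"`; defaults to the table's
#'   `"direction"` attribute when present.
#' @return single-row data.frame.
#' @export
rank_extremes <- function(table, direction = attr(table, "direction")) {
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  direction <- match.arg(direction, c("down", "up"))
  key <- if (direction == "down") table$rsc else -table$rsc
  ord <- order(key, table$gene)
  table[ord[1L], , drop = FALSE]
}

#' Pearson correlation between samples
#'
#' Correlates the NSpC profiles of every pair of samples over the shared
#' protein index. The diagonal is exactly 1 and the matrix symmetric.
#'
#' @param nspc numeric matrix (proteins x samples), e.g. from
#'   [normalize_counts()]; needs at least 2 samples and 2 proteins.
#' @return symmetric correlation matrix over samples.
#' @export
sample_correlation_matrix <- function(nspc) {
  if (ncol(nspc) < 2 || nrow(nspc) < 2)
    stop("need at least 2 samples and 2 proteins", call. = FALSE)
  v <- apply(nspc, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(nspc)[v == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(nspc)
  diag(r) <- 1
  r
}

#' Average-linkage clustering of a sample correlation matrix
#'
#' Agglomerative clustering on the distance `1 - r` with average (UPGMA)
#' linkage. Leaf order is deterministic: `stats::hclust` ordering with ties
#' resolved by the input (sample-id) order of the distance matrix.
#'
#' @param r symmetric correlation matrix as from
#'   [sample_correlation_matrix()].
#' @return list with `hclust` (the tree), `order` (leaf order, sample ids),
#'   and `matrix` (the correlation matrix reordered for heat-map display).
#' @export
hierarchical_cluster <- function(r) {
  if (!isSymmetric(unname(r), tol = 1e-8))
    stop("correlation matrix is not symmetric", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  ord <- hc$order
  list(hclust = hc, order = rownames(r)[ord],
       matrix = r[ord, ord, drop = FALSE])
}

#' Export deduplicated gene-symbol lists
#'
#' Writes one gene symbol per line (first-occurrence order, duplicates
#' removed) for pasting into external network-analysis tools.
#'
#' @param tables named list of data.frames with a `gene` column.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
export_gene_lists <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0("genes_", nm, ".txt"))
    writeLines(unique(tables[[nm]]$gene), path)
    path
  }, "")
  invisible(paths)
}
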