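#' Read a spectral-count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds protein accessions
#' and whose remaining column names are sample ids in the
#' `condition.compartment.bioN.techM` dialect. Cells must be non-negative
#' integers; duplicate accessions or sample ids and malformed ids are
#' rejected with the offending location.
#'
#' @param path input file.
#' @return an [spc_set].
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("count matrix needs an accession column and >= 1 sample", call. = FALSE)
  acc <- as.character(tab[[1]])
  if (anyDuplicated(acc))
    stop("duplicate accession at row ",
         which(duplicated(acc))[1L], ": ", acc[duplicated(acc)][1L],
         call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop(sprintf("non-integer or negative count at row %d, column '%s'",
                   bad[1L], colnames(m)[j]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- acc
  spc_set(m)
}

#' Write a spectral-count matrix as TSV
#'
#' @param x an [spc_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "spc_set"))
  out <- data.frame(accession = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

results_columns <- c("accession", "compartment", "n_ctrl", "t_ctrl",
                     "n_kd", "t_kd", "rsc", "p_raw", "q_bh", "call")

#' Write a differential-results table as TSV
#'
#' Columns are written in a fixed order; floating-point values are printed
#' at 6 significant digits, so re-reading reproduces values to print
#' precision.
#'
#' @param results data.frame from [spc_differential()] /
#'   [call_differential()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  cols <- intersect(results_columns, names(results))
  out <- results[, cols, drop = FALSE]
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential-results table written by [write_results_table()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Run the full discovery pipeline
#'
#' Drives the stages quantify -> test -> curate -> report for every
#' compartment of a data set, writing all artifacts into `out_dir`:
#' per-compartment differential results, retained (curated) tables,
#' per-rule curation ledgers, category distributions, the sample-correlation
#' matrix with its clustering order, per-direction gene lists, and a run
#' log. All outputs are deterministic given the configuration (and its
#' simulation seed), so repeated runs are byte-identical.
#'
#' @param config either a list or a path to a JSON file with entries:
#'   \describe{
#'     \item{simulation}{list of [sim_config()] arguments (mutually exclusive
#'       with `counts`).}
#'     \item{counts}{path to a count-matrix TSV read with
#'       [read_count_matrix()].}
#'     \item{proteins}{optional path to a protein-metadata TSV (columns
#'       `accession`, `gene`, `description`).}
#'     \item{category_map}{optional path to a TSV with columns `gene`,
#'       `category`.}
#'     \item{conditions}{reference and knockdown condition labels
#'       (default `c("control", "kd")`).}
#'     \item{f, rsc_threshold, alpha, use_adjusted}{analysis thresholds
#'       (defaults 0.5, 1.8, 0.05, TRUE).}
#'   }
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the per-compartment results, curation
#'   reports, and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  has_sim <- !is.null(config$simulation)
  has_counts <- !is.null(config$counts)
  if (has_sim == has_counts)
    stop("config must contain exactly one of 'simulation' or 'counts'",
         call. = FALSE)

  truth <- NULL
  if (has_sim) {
    cfg <- do.call(sim_config, as.list(config$simulation))
    sim <- simulate_dataset(cfg)
    x <- sim$data; proteins <- sim$proteins; truth <- sim$truth
    conditions <- cfg$conditions
    write_count_matrix(x, file.path(out_dir, "counts.tsv"))
    utils::write.table(proteins, file.path(out_dir, "proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("simulate: %d proteins, %d samples, seed %d",
        nrow(x$counts), ncol(x$counts), cfg$seed)
  } else {
    x <- read_count_matrix(config$counts)
    proteins <- if (!is.null(config$proteins))
      utils::read.delim(config$proteins, stringsAsFactors = FALSE,
                        quote = "")
    else data.frame(accession = rownames(x$counts),
                    gene = rownames(x$counts),
                    description = "", stringsAsFactors = FALSE)
    conditions <- config$conditions
    if (is.null(conditions)) conditions <- c("control", "kd")
    say("read: %d proteins, %d samples from %s",
        nrow(x$counts), ncol(x$counts), config$counts)
  }

  f <- config$f %||% 0.5
  rsc_threshold <- config$rsc_threshold %||% 1.8
  alpha <- config$alpha %||% 0.05
  use_adjusted <- config$use_adjusted %||% TRUE

  cat_map <- if (!is.null(config$category_map))
    utils::read.delim(config$category_map, stringsAsFactors = FALSE,
                      quote = "")
  else NULL

  compartments <- unique(x$samples$compartment)
  results <- list(); reports <- list(); gene_tables <- list()
  for (comp in compartments) {
    res <- spc_differential(x, comp, conditions = conditions, f = f,
                            rsc_threshold = rsc_threshold, alpha = alpha,
                            use_adjusted = use_adjusted)
    write_results_table(res, file.path(out_dir,
                                       sprintf("results_%s.tsv", comp)))
    cur <- apply_exclusion_rules(res, proteins)
    write_results_table(cur$retained,
                        file.path(out_dir,
                                  sprintf("retained_%s.tsv", comp)))
    write_curation_report(cur$report,
                          file.path(out_dir,
                                    sprintf("curation_%s.tsv", comp)))
    say("test/curate [%s]: %d tested, %d called, %d retained", comp,
        nrow(res), sum(res$call != "none"), nrow(cur$retained))
    results[[comp]] <- res
    reports[[comp]] <- cur$report
    ret <- cur$retained
    ret <- merge(ret, proteins[, intersect(c("accession", "gene"),
                                           names(proteins))],
                 by = "accession", sort = FALSE)
    if (is.null(ret$gene)) ret$gene <- ret$accession
    for (dir in c("up", "down")) {
      sub <- ret[ret$call == dir, , drop = FALSE]
      gene_tables[[paste(comp, dir, sep = "_")]] <- sub
      if (nrow(sub) > 0 && !is.null(cat_map)) {
        ann <- assign_categories(sub, cat_map)
        dist <- category_distribution(ann)
        utils::write.table(dist,
                           file.path(out_dir,
                                     sprintf("categories_%s_%s.tsv",
                                             comp, dir)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  nspc <- normalize_counts(x)
  r <- sample_correlation_matrix(nspc)
  cl <- hierarchical_cluster(r)
  utils::write.table(
    data.frame(sample_id = rownames(cl$matrix), cl$matrix,
               check.names = FALSE),
    file.path(out_dir, "sample_correlation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cl$order, file.path(out_dir, "sample_order.txt"))
  say("report: correlation matrix over %d samples", ncol(nspc))

  export_gene_lists(gene_tables, out_dir)
  writeLines(log, file.path(out_dir, "pipeline.log"))
  invisible(list(results = results, curation = reports, truth = truth,
                 correlation = r, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
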