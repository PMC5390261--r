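#' Spectral-count data set
#'
#' Bundles a protein x sample matrix of spectral counts with the sample
#' annotation needed downstream (condition, compartment, biological and
#' technical replicate indices), in the spirit of `edgeR::DGEList`.
#'
#' Sample ids follow the dialect `condition.compartment.bioN.techM`
#' (e.g. `"control.cell.bio1.tech2"`). If `samples` is omitted it is decoded
#' from the column names with [parse_sample_ids()].
#'
#' @param counts integer matrix of spectral counts; rownames are protein
#'   accessions, colnames are sample ids.
#' @param samples optional data.frame with columns `sample_id`, `condition`,
#'   `compartment`, `biological`, `technical`, one row per column of `counts`.
#' @return An object of class `"spc_set"`: a list with elements `counts` and
#'   `samples`.
#' @examples
#' m <- matrix(c(4L, 6L, 1L, 9L), 2, 2,
#'             dimnames = list(c("P1", "P2"),
#'                             c("control.cell.bio1.tech1",
#'                               "kd.cell.bio1.tech1")))
#' spc_set(m)
#' @export
spc_set <- function(counts, samples = NULL) {
  if (!is.matrix(counts))
    stop("'counts' must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have accession rownames and sample-id colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate accession in counts: ",
         rownames(counts)[duplicated(rownames(counts))][1L], call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id in counts: ",
         colnames(counts)[duplicated(colnames(counts))][1L], call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(samples))
    samples <- parse_sample_ids(colnames(counts))
  stopifnot(identical(samples$sample_id, colnames(counts)))
  structure(list(counts = counts, samples = samples), class = "spc_set")
}

#' @export
print.spc_set <- function(x, ...) {
  cat(sprintf("spc_set: %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$condition, x$samples$compartment)
  cat("samples per condition x compartment:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.spc_set <- function(x) dim(x$counts)

#' Decode sample ids of the form condition.compartment.bioN.techM
#'
#' @param ids character vector of sample ids.
#' @return data.frame with columns `sample_id`, `condition`, `compartment`,
#'   `biological`, `technical`.
#' @export
parse_sample_ids <- function(ids) {
  pat <- "^([^.]+)\\.([^.]+)\\.bio([0-9]+)\\.tech([0-9]+)$"
  bad <- !grepl(pat, ids)
  if (any(bad))
    stop("malformed sample id(s): ", paste(ids[bad], collapse = ", "),
         " (expected condition.compartment.bioN.techM)", call. = FALSE)
  data.frame(
    sample_id   = ids,
    condition   = sub(pat, "\\1", ids),
    compartment = sub(pat, "\\2", ids),
    biological  = as.integer(sub(pat, "\\3", ids)),
    technical   = as.integer(sub(pat, "\\4", ids)),
    stringsAsFactors = FALSE
  )
}

make_sample_id <- function(condition, compartment, biological, technical) {
  sprintf("%s.%s.bio%d.tech%d", condition, compartment, biological, technical)
}
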