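#' Packaged curated protein tables
#'
#' Returns one of the six curated differential-protein tables shipped with
#' the package (per compartment and direction), transcribed verbatim from
#' the published study tables, including context rows whose |Rsc| falls
#' below the 1.8 calling threshold. These tables are reporting inputs only;
#' they are never used to validate the differential-calling thresholds.
#'
#' @param name one of `"cell_down"`, `"cell_up"`, `"secretome_down"`,
#'   `"secretome_up"`, `"xenograft_down"`, `"xenograft_up"`.
#' @return data.frame with columns `category`, `gene`, `description`, `rsc`
#'   and attributes `compartment` and `direction`.
#' @examples
#' head(curated_fixture("cell_down"))
#' @export
curated_fixture <- function(name = c("cell_down", "cell_up",
                                     "secretome_down", "secretome_up",
                                     "xenograft_down", "xenograft_up")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("curated_", name, ".tsv"),
                      package = "spcdelta", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           encoding = "UTF-8")
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  attr(tab, "compartment") <- parts[1]
  attr(tab, "direction") <- parts[2]
  tab
}

#' Functional-category map derived from the packaged tables
#'
#' Gene symbol to category lookup pooled over the requested fixture tables;
#' the first occurrence wins when a symbol appears with different categories
#' in different compartments.
#'
#' @param names fixture names to pool (default: all six).
#' @return data.frame with columns `gene` and `category`.
#' @export
fixture_category_map <- function(names = c("cell_down", "cell_up",
                                           "secretome_down", "secretome_up",
                                           "xenograft_down",
                                           "xenograft_up")) {
  maps <- lapply(names, function(nm) {
    tab <- curated_fixture(nm)
    tab[, c("gene", "category")]
  })
  out <- do.call(rbind, maps)
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
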