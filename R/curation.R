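#' A single curation (exclusion) rule
#'
#' @param name rule identifier.
#' @param keywords case-insensitive substrings matched against the protein
#'   description (ignored by the built-in `not_significant` and
#'   `no_accession` rules, which test the differential call and the reported
#'   accession instead).
#' @param compartments compartment labels the rule applies to, or `"all"`.
#' @return list of class `"curation_rule"`.
#' @export
curation_rule <- function(name, keywords = character(0),
                          compartments = "all") {
  structure(list(name = name, keywords = keywords,
                 compartments = compartments),
            class = "curation_rule")
}

#' Default protein selection rules
#'
#' The ordered exclusion rules applied after differential testing:
#' non-significant proteins first, then the contaminant classes — keratins
#' (description contains "keratin" or gene symbol starts with `KRT`), entries
#' with no reported accession, peptide fragments, putative uncharacterized
#' proteins, cDNA-like entries, and (in the xenograft compartment only,
#' where excision can carry over mouse muscle tissue) skeletal-muscle
#' proteins. The skeletal-muscle keyword is deliberately narrow — the
#' description must contain "skeletal muscle" — so that genuinely tumor-borne
#' muscle-associated gene products (tropomyosins, nebulin) are not removed.
#'
#' @param include_significance include the leading `not_significant` rule.
#' @return ordered list of [curation_rule()] objects.
#' @export
default_curation_rules <- function(include_significance = TRUE) {
  rules <- list(
    curation_rule("keratin", "keratin"),
    curation_rule("no_accession"),
    curation_rule("fragment", "fragment"),
    curation_rule("uncharacterized", "putative uncharacter"),
    curation_rule("cdna_like", "cdna"),
    curation_rule("skeletal_muscle", "skeletal muscle",
                  compartments = "xenograft")
  )
  if (include_significance)
    rules <- c(list(curation_rule("not_significant")), rules)
  rules
}

rule_matches <- function(rule, results, proteins) {
  n <- nrow(results)
  hit <- switch(rule$name,
    not_significant = {
      if (is.null(results$call))
        stop("'not_significant' rule needs a 'call' column", call. = FALSE)
      results$call == "none"
    },
    no_accession = {
      acc <- proteins$reported_accession
      if (is.null(acc)) acc <- proteins$accession
      !nzchar(trimws(acc))
    },
    {
      desc <- tolower(proteins$description)
      extra <- if (rule$name == "keratin" && !is.null(proteins$gene))
        startsWith(toupper(proteins$gene), "KRT") else rep(FALSE, n)
      kw <- tolower(rule$keywords)
      hit <- rep(FALSE, n)
      for (k in kw) hit <- hit | grepl(k, desc, fixed = TRUE)
      hit | extra
    })
  if (!identical(rule$compartments, "all"))
    hit <- hit & results$compartment %in% rule$compartments
  hit
}

#' Apply the protein selection rules
#'
#' Removes proteins that fail the significance call or match any applicable
#' contaminant rule, attributing each exclusion to the first matching rule in
#' order. Rule order changes attribution, never the retained set.
#'
#' @param results differential results ([spc_differential()]); must contain
#'   `accession` and `compartment` (and `call` if the `not_significant` rule
#'   is present).
#' @param proteins protein metadata with `accession`, `description`, and
#'   optionally `gene` and `reported_accession`; every tested accession must
#'   be present.
#' @param rules ordered list of [curation_rule()]s
#'   (default [default_curation_rules()]).
#' @return list with `retained` (the surviving rows of `results`) and
#'   `report`, a `"curation_report"`: per-rule excluded counts and accession
#'   lists plus the retained count.
#' @export
apply_exclusion_rules <- function(results, proteins,
                                  rules = default_curation_rules()) {
  idx <- match(results$accession, proteins$accession)
  if (anyNA(idx))
    stop("missing protein metadata for accession(s): ",
         paste(unique(results$accession[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  prot <- proteins[idx, , drop = FALSE]
  excluded_by <- rep(NA_character_, nrow(results))
  for (rule in rules) {
    hit <- rule_matches(rule, results, prot) & is.na(excluded_by)
    excluded_by[hit] <- rule$name
  }
  keep <- is.na(excluded_by)
  rule_names <- vapply(rules, `[[`, "", "name")
  counts <- vapply(rule_names,
                   function(r) sum(excluded_by == r, na.rm = TRUE), 0L)
  accs <- lapply(rule_names, function(r)
    results$accession[!is.na(excluded_by) & excluded_by == r])
  names(accs) <- rule_names
  report <- structure(list(input = nrow(results),
                           retained = sum(keep),
                           excluded = counts,
                           accessions = accs),
                      class = "curation_report")
  retained <- results[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation report\n")
  cat(sprintf("  input proteins: %d\n", x$input))
  for (r in names(x$excluded))
    cat(sprintf("  excluded (%s): %d\n", r, x$excluded[[r]]))
  cat(sprintf("  retained: %d\n", x$retained))
  invisible(x)
}

#' @export
as.data.frame.curation_report <- function(x, ...) {
  data.frame(rule = c(names(x$excluded), "retained"),
             count = c(unname(x$excluded), x$retained),
             stringsAsFactors = FALSE)
}

#' Write a curation report as TSV
#'
#' @param report a `"curation_report"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
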