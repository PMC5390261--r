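#' Filter peptide-spectrum matches on identification probability
#'
#' Retains PSMs whose probability is strictly greater than `min_probability`
#' (default 0.95, the conventional PeptideProphet acceptance level). The
#' inequality is strict: a record at exactly the threshold is removed. Input
#' order is preserved.
#'
#' @param psms data.frame with at least columns `spectrum_id`, `peptide`,
#'   `accessions` (`";"`-separated when a peptide maps to several proteins),
#'   `probability` in \[0, 1\], `decoy` (logical), `significant` (logical).
#' @param min_probability probability cutoff (strict `>`).
#' @return the filtered PSM table.
#' @export
filter_psms <- function(psms, min_probability = 0.95) {
  check_psm_table(psms)
  psms[psms$probability > min_probability, , drop = FALSE]
}

check_psm_table <- function(psms) {
  need <- c("peptide", "accessions", "probability")
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("PSM table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(psms) == 0) return(invisible(psms))
  if (any(psms$probability < 0 | psms$probability > 1))
    stop("PSM probabilities must lie in [0, 1]", call. = FALSE)
  if (any(!nzchar(psms$peptide)))
    stop("PSM peptides must be non-empty", call. = FALSE)
  if (any(!nzchar(psms$accessions)))
    stop("PSM mapped accessions must be non-empty", call. = FALSE)
  invisible(psms)
}

split_accessions <- function(x) strsplit(x, ";", fixed = TRUE)

# Minimal set cover over indistinguishable-peptide-set units.
# Exact exhaustive search for small instances (the tie among equally small
# covers is broken by lexicographic unit order, units ordered by lead
# accession); deterministic greedy beyond that.
minimal_set_cover <- function(unit_set, all_peps, unit_lead) {
  nu <- length(unit_set)
  ord_units <- order(unit_lead)
  if (nu <= 16L && length(all_peps) <= 30L) {
    masks <- vapply(unit_set, function(s)
      sum(bitwShiftL(1L, match(s, all_peps) - 1L)), 0L)
    full <- sum(bitwShiftL(1L, seq_along(all_peps) - 1L))
    best <- NULL
    for (size in seq_len(nu)) {
      combos <- utils::combn(ord_units, size, simplify = FALSE)
      for (cmb in combos) {
        m <- 0L
        for (i in cmb) m <- bitwOr(m, masks[i])
        if (m == full) { best <- cmb; break }
      }
      if (!is.null(best)) break
    }
    return(best)
  }
  uncovered <- all_peps
  selected <- integer(0)
  remaining <- seq_len(nu)
  while (length(uncovered) > 0) {
    gain <- vapply(remaining,
                   function(i) sum(unit_set[[i]] %in% uncovered), 0L)
    total <- lengths(unit_set[remaining])
    ordsel <- order(-gain, -total, unit_lead[remaining])
    pick <- remaining[ordsel[1L]]
    selected <- c(selected, pick)
    uncovered <- setdiff(uncovered, unit_set[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Group proteins by parsimony
#'
#' Infers the minimal set of protein groups explaining all observed peptides.
#' Proteins with identical peptide sets are merged into a single
#' indistinguishable unit; proteins whose peptide set is contained in a
#' selected group's set are absorbed as members. For small problems (up to 16
#' distinguishable units and 30 peptides) the minimum set cover is found
#' exactly by exhaustive search over unit subsets, smallest cover first with
#' deterministic lexicographic tie-breaking; larger problems use greedy set
#' cover with ties broken by most uncovered peptides, then most peptides
#' overall, then lexicographically smallest accession.
#'
#' Each protein's probability is combined from its PSMs as
#' `1 - prod(1 - best probability per peptide)`; a group's probability is the
#' maximum over its members, and a group is flagged decoy only when every
#' member is decoy (a member is decoy when all of its PSMs are).
#'
#' @param psms a PSM table (normally already passed through [filter_psms()]).
#' @return data.frame with columns `lead_accession`, `member_accessions`
#'   (`";"`-separated), `n_peptides`, `unique_peptide_count` (peptides mapping
#'   to exactly one surviving group), `probability`, `decoy`.
#' @export
group_proteins_parsimony <- function(psms) {
  check_psm_table(psms)
  if (nrow(psms) == 0)
    return(data.frame(lead_accession = character(0),
                      member_accessions = character(0),
                      n_peptides = integer(0),
                      unique_peptide_count = integer(0),
                      probability = numeric(0), decoy = logical(0)))
  accs <- split_accessions(psms$accessions)
  long <- data.frame(
    accession = unlist(accs),
    peptide = rep(psms$peptide, lengths(accs)),
    probability = rep(psms$probability, lengths(accs)),
    decoy = rep(if (is.null(psms$decoy)) FALSE else psms$decoy,
                lengths(accs)),
    stringsAsFactors = FALSE
  )
  pep_sets <- lapply(split(long$peptide, long$accession),
                     function(p) sort(unique(p)))
  prot_decoy <- vapply(split(long$decoy, long$accession), all, logical(1))
  # best probability per (protein, peptide), combined naively per protein
  prot_prob <- vapply(split(long, long$accession), function(d) {
    best <- vapply(split(d$probability, d$peptide), max, numeric(1))
    1 - prod(1 - best)
  }, numeric(1))

  # merge proteins with identical peptide sets into indistinguishable units
  key <- vapply(pep_sets, paste, "", collapse = "\r")
  units <- split(names(pep_sets), key)
  unit_members <- lapply(units, sort)
  unit_set <- pep_sets[vapply(unit_members, `[`, "", 1L)]
  unit_lead <- vapply(unit_members, `[`, "", 1L)

  # minimal cover of all peptides over the indistinguishable units
  all_peps <- sort(unique(long$peptide))
  selected <- minimal_set_cover(unit_set, all_peps, unit_lead)
  remaining <- setdiff(seq_along(unit_set), selected)
  # absorb unselected units into the first selected superset group
  members <- unit_members[selected]
  for (i in remaining) {
    for (j in seq_along(selected)) {
      if (all(unit_set[[i]] %in% unit_set[[selected[j]]])) {
        members[[j]] <- sort(c(members[[j]], unit_members[[i]]))
        break
      }
    }
  }
  sets <- unit_set[selected]
  # peptides explained by exactly one surviving group are 'unique'
  pep_hits <- table(unlist(sets))
  uniq_count <- vapply(sets, function(s) sum(pep_hits[s] == 1L), 0L)

  out <- data.frame(
    lead_accession = unit_lead[selected],
    member_accessions = vapply(members, paste, "", collapse = ";"),
    n_peptides = lengths(sets),
    unique_peptide_count = as.integer(uniq_count),
    probability = vapply(members, function(m) max(prot_prob[m]), numeric(1)),
    decoy = vapply(members, function(m) all(prot_decoy[m]), logical(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$lead_accession), , drop = FALSE]
}

#' Accept protein groups under probability, peptide and decoy-FDR constraints
#'
#' Retains groups with probability strictly above `min_protein_probability`
#' and at least `min_unique_peptides` unique peptides, then checks the decoy
#' false-discovery rate, estimated as retained decoys / retained targets. If
#' the FDR exceeds `max_fdr`, the probability threshold is raised to the
#' smallest retained probability value that brings the FDR within bound.
#' Decoy groups are dropped from the returned table; the probability
#' threshold finally applied is attached as attribute
#' `"probability_threshold"` and the achieved FDR as `"decoy_fdr"`.
#'
#' @param groups output of [group_proteins_parsimony()].
#' @param min_protein_probability protein-level probability cutoff
#'   (strict `>`, default 0.99).
#' @param min_unique_peptides minimum unique peptides (default 2).
#' @param max_fdr decoy FDR bound (default 0.01).
#' @return the accepted target groups.
#' @export
accept_protein_groups <- function(groups,
                                  min_protein_probability = 0.99,
                                  min_unique_peptides = 2L,
                                  max_fdr = 0.01) {
  if (nrow(groups) > 0 && all(groups$decoy))
    stop("all protein groups are decoys; decoy FDR is uninterpretable",
         call. = FALSE)
  keep <- groups$probability > min_protein_probability &
    groups$unique_peptide_count >= min_unique_peptides
  cur <- groups[keep, , drop = FALSE]
  thr <- min_protein_probability
  decoy_fdr <- function(g) {
    nt <- sum(!g$decoy)
    if (nt == 0) Inf else sum(g$decoy) / nt
  }
  if (nrow(cur) > 0 && decoy_fdr(cur) > max_fdr) {
    # escalate: sweep the retained probabilities from the bottom up
    for (p in sort(unique(cur$probability))) {
      cand <- cur[cur$probability > p, , drop = FALSE]
      if (nrow(cand) == 0) { cur <- cand; thr <- p; break }
      if (decoy_fdr(cand) <= max_fdr) { cur <- cand; thr <- p; break }
    }
  }
  out <- cur[!cur$decoy, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "probability_threshold") <- thr
  attr(out, "decoy_fdr") <- if (nrow(cur)) {
    f <- decoy_fdr(cur); if (is.finite(f)) f else NA_real_
  } else 0
  out
}

#' Simulate a PSM table exercising the identification filters
#'
#' Generates target and decoy peptide-spectrum matches with configurable
#' probability distributions. This is plumbing for testing the acceptance
#' pipeline, not a model of search-engine scoring: target PSM probabilities
#' are drawn from `Beta(target_shape, 1)` (concentrated near 1), decoys from
#' `Beta(1, decoy_shape)` (concentrated near 0).
#'
#' @param n_proteins number of target proteins.
#' @param peptides_per_protein expected peptides per protein (Poisson, min 1).
#' @param decoy_fraction fraction of additional decoy proteins.
#' @param target_shape,decoy_shape beta-distribution shapes.
#' @param seed integer seed.
#' @return a PSM table as consumed by [filter_psms()].
#' @export
simulate_psm_table <- function(n_proteins = 100L, peptides_per_protein = 4,
                               decoy_fraction = 0.1, target_shape = 20,
                               decoy_shape = 10, seed = 1L) {
  set.seed(seed)
  n_dec <- round(decoy_fraction * n_proteins)
  acc <- c(sprintf("TGT%04d", seq_len(n_proteins)),
           sprintf("DECOY%04d", seq_len(n_dec)))
  is_dec <- c(rep(FALSE, n_proteins), rep(TRUE, n_dec))
  rows <- lapply(seq_along(acc), function(i) {
    k <- max(1L, stats::rpois(1, peptides_per_protein))
    data.frame(
      spectrum_id = sprintf("%s.sp%d", acc[i], seq_len(k)),
      peptide = sprintf("PEP%s%02d", acc[i], seq_len(k)),
      accessions = acc[i],
      probability = if (is_dec[i]) stats::rbeta(k, 1, decoy_shape)
                    else stats::rbeta(k, target_shape, 1),
      decoy = is_dec[i],
      significant = TRUE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
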