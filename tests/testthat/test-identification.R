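test_that("PSM probability filter is strict, order-preserving, idempotent", {
  psms <- psm_rows(c("a", "b", "c"), c("P1", "P2", "P3"),
                   prob = c(0.96, 0.95, 0.99))
  kept <- filter_psms(psms)
  expect_equal(kept$peptide, c("a", "c"))  # 0.95 removed: strict >

  probs <- 0.90 + (1:100) / 1000
  many <- psm_rows(sprintf("p%03d", 1:100), "P1", prob = probs)
  kept2 <- filter_psms(many)
  expect_equal(nrow(kept2), sum(probs > 0.95))      # brute-force count
  expect_identical(kept2$peptide, many$peptide[probs > 0.95])
  expect_identical(filter_psms(kept2), kept2)       # idempotent

  # monotone: raising the cutoff never enlarges the retained set
  for (cut in c(0.93, 0.97, 0.995))
    expect_true(all(filter_psms(many, cut)$peptide %in%
                      filter_psms(many, 0.92)$peptide))

  expect_equal(nrow(filter_psms(many[0, ])), 0L)
  expect_error(filter_psms(transform(psms, probability = c(1.2, .5, .5))),
               "\\[0, 1\\]")
})

test_that("parsimony grouping merges, absorbs, and is minimal", {
  # disjoint peptide sets: two groups
  g <- group_proteins_parsimony(psm_rows(c("a", "b"), c("P1", "P2")))
  expect_equal(nrow(g), 2L)

  # identical peptide sets: one group carrying both accessions
  g <- group_proteins_parsimony(psm_rows(c("a", "b"), c("P1;P2", "P1;P2")))
  expect_equal(nrow(g), 1L)
  expect_equal(g$member_accessions, "P1;P2")

  # subset absorbed under the covering lead
  g <- group_proteins_parsimony(psm_rows(c("p1", "p2", "p3"),
                                         c("A", "A;B", "A")))
  expect_equal(g$lead_accession, "A")
  expect_equal(g$member_accessions, "A;B")
  expect_equal(g$unique_peptide_count, 3L)

  # shared peptide between two surviving groups is not unique to either
  g <- group_proteins_parsimony(psm_rows(c("a", "s", "b", "s"),
                                         c("A", "A", "B", "B")))
  expect_equal(sort(g$lead_accession), c("A", "B"))
  expect_equal(g$unique_peptide_count, c(1L, 1L))
})

test_that("group count equals the exhaustive minimum set cover on small instances", {
  set.seed(71)
  for (case in 1:25) {
    n_prot <- sample(2:6, 1)
    n_pep <- sample(3:10, 1)
    peps <- sprintf("pep%02d", seq_len(n_pep))
    sets <- lapply(seq_len(n_prot), function(i)
      sort(sample(peps, sample(seq_len(n_pep), 1))))
    # every peptide observed: PSMs list each peptide with all its proteins
    prot <- sprintf("PR%02d", seq_len(n_prot))
    rows <- do.call(rbind, lapply(seq_len(n_pep), function(j) {
      owners <- prot[vapply(sets, function(s) peps[j] %in% s, TRUE)]
      if (!length(owners)) return(NULL)
      psm_rows(peps[j], paste(owners, collapse = ";"))
    }))
    if (is.null(rows)) next
    g <- group_proteins_parsimony(rows)
    observed <- sort(unique(rows$peptide))
    sets_obs <- lapply(sets, intersect, observed)
    keep <- lengths(sets_obs) > 0
    expect_equal(nrow(g),
                 oracle_min_cover_size(sets_obs[keep], observed),
                 info = paste("case", case))
  }
})

test_that("protein acceptance applies probability, peptide and FDR gates", {
  grp <- function(acc, prob, uniq, dec = FALSE)
    data.frame(lead_accession = acc, member_accessions = acc,
               n_peptides = uniq, unique_peptide_count = uniq,
               probability = prob, decoy = dec, stringsAsFactors = FALSE)

  base <- rbind(grp("A", 0.995, 2), grp("B", 0.999, 1), grp("C", 0.98, 5))
  acc <- accept_protein_groups(base)
  expect_equal(acc$lead_accession, "A")   # B fails peptides, C probability

  # FDR escalation matches a brute-force threshold sweep
  set.seed(12)
  tgt <- grp(sprintf("T%03d", 1:99), sort(runif(99, 0.991, 0.9999)), 2)
  dec <- grp(c("D1", "D2"), c(0.9912, 0.9985), 2, dec = TRUE)
  groups <- rbind(tgt, dec)
  out <- accept_protein_groups(groups, max_fdr = 0.01)
  thr <- attr(out, "probability_threshold")
  # brute force over all candidate thresholds
  cand <- sort(unique(groups$probability[groups$probability > 0.99]))
  sweep_thr <- 0.99
  for (p in c(0.99, cand)) {
    k <- groups$probability > p & groups$unique_peptide_count >= 2
    nt <- sum(k & !groups$decoy); nd <- sum(k & groups$decoy)
    if (nt > 0 && nd / nt <= 0.01) { sweep_thr <- p; break }
  }
  expect_equal(thr, sweep_thr)
  k <- groups$probability > thr
  expect_equal(sum(groups$decoy[k]) / sum(!groups$decoy[k]),
               attr(out, "decoy_fdr"))
  expect_lte(attr(out, "decoy_fdr"), 0.01)
  expect_false(any(out$decoy))

  # idempotence on own output (decoys gone, thresholds already met)
  again <- accept_protein_groups(out, max_fdr = 0.01)
  expect_equal(again$lead_accession, out$lead_accession)

  # monotonicity: stricter probability never enlarges the accepted set
  strict <- accept_protein_groups(groups, min_protein_probability = 0.995)
  expect_true(all(strict$lead_accession %in% out$lead_accession |
                    strict$probability > thr))

  expect_error(accept_protein_groups(grp("D", 0.999, 3, dec = TRUE)),
               "decoy")
})
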