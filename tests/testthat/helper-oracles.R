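# Independent oracles used to validate the analytic code paths. These are
# deliberately written from first principles (enumeration, direct
# definitions, brute force) and never call the implementation under test.

# Two-sided Fisher p by exhaustive hypergeometric enumeration in log space.
oracle_fisher <- function(n1, t1, n2, t2) {
  m <- n1 + n2
  lo <- max(0, m - t2); hi <- min(m, t1)
  k <- lo:hi
  d <- exp(lchoose(t1, k) + lchoose(t2, m - k) - lchoose(t1 + t2, m))
  min(1, sum(d[d <= d[n1 - lo + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg straight from the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# Brute-force UPGMA: merge heights from repeated closest-pair search with
# mean pairwise distances.
oracle_average_linkage <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(j, i) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Exhaustive minimum set cover size.
oracle_min_cover_size <- function(sets, universe) {
  n <- length(sets)
  for (size in seq_len(n)) {
    for (cmb in utils::combn(n, size, simplify = FALSE)) {
      if (all(universe %in% unlist(sets[cmb]))) return(size)
    }
  }
  n
}

# Small PSM-table builder.
psm_rows <- function(pep, acc, prob = 0.99, decoy = FALSE) {
  data.frame(spectrum_id = paste0("s", seq_along(pep), ".", pep),
             peptide = pep, accessions = acc, probability = prob,
             decoy = decoy, significant = TRUE, stringsAsFactors = FALSE)
}

# spc_set from a plain matrix: first n_ctrl columns control, rest knockdown.
toy_spc <- function(counts, n_ctrl, compartment = "cell") {
  n_kd <- ncol(counts) - n_ctrl
  ids <- c(sprintf("control.%s.bio%d.tech1", compartment, seq_len(n_ctrl)),
           sprintf("kd.%s.bio%d.tech1", compartment, seq_len(n_kd)))
  colnames(counts) <- ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%03d", seq_len(nrow(counts)))
  spc_set(counts)
}
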