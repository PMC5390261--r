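#' Two-sided Fisher exact test for pooled spectral counts
#'
#' For each protein, tests the 2x2 table
#' `[[n_ctrl, t_ctrl - n_ctrl], [n_kd, t_kd - n_kd]]` against independence.
#' The two-sided p-value follows the minimum-likelihood convention (as in
#' `stats::fisher.test`): it sums the hypergeometric probabilities of all
#' outcomes no more probable than the observed one (with the customary
#' `1 + 1e-7` relative tolerance for ties). Degenerate margins (for example
#' `n_ctrl = n_kd = 0`) give p = 1.
#'
#' All arguments are recycled to a common length; proteins sharing the same
#' margins share one evaluation of the hypergeometric support, so the
#' function is fast for whole-proteome vectors.
#'
#' @param n_ctrl,t_ctrl,n_kd,t_kd non-negative integer vectors with
#'   `n <= t` in each condition; `t_ctrl + t_kd > 0`.
#' @return numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_protein(5, 1000, 20, 1000)
#' @export
fisher_exact_protein <- function(n_ctrl, t_ctrl, n_kd, t_kd) {
  k <- max(length(n_ctrl), length(t_ctrl), length(n_kd), length(t_kd))
  n1 <- rep_len(n_ctrl, k); t1 <- rep_len(t_ctrl, k)
  n2 <- rep_len(n_kd, k);   t2 <- rep_len(t_kd, k)
  if (any(n1 < 0) || any(n2 < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(n1 > t1) || any(n2 > t2))
    stop("count exceeds total", call. = FALSE)
  if (any(t1 + t2 == 0))
    stop("both totals are zero", call. = FALSE)
  m <- n1 + n2                 # first-column margin
  p <- numeric(k)
  key <- paste(t1, t2, m, sep = "/")
  for (grp in split(seq_len(k), key)) {
    i1 <- grp[1L]
    lo <- max(0L, m[i1] - t2[i1]); hi <- min(m[i1], t1[i1])
    d <- stats::dhyper(lo:hi, m[i1], t1[i1] + t2[i1] - m[i1], t1[i1])
    ord <- order(d)
    cs <- cumsum(d[ord])
    ds <- d[ord]
    thr <- d[n1[grp] - lo + 1L] * (1 + 1e-7)
    idx <- findInterval(thr, ds)
    p[grp] <- pmin(1, cs[idx])
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, mapped back to input order and
#' capped at 1. Delegates to `stats::p.adjust(method = "BH")` after
#' validating the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) && (any(is.na(p)) || any(p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-protein differential test for one compartment
#'
#' Pools replicates per condition within the compartment, computes Rsc,
#' Fisher exact p-values on the pooled counts, BH-adjusted q-values (within
#' the compartment), and differential calls.
#'
#' @param x an [spc_set].
#' @param compartment compartment label to analyse.
#' @param conditions length-2 character: reference (control) condition first,
#'   knockdown second.
#' @param f Rsc pseudocount.
#' @param rsc_threshold,alpha,use_adjusted see [call_differential()].
#' @return data.frame with columns `accession`, `compartment`, `n_ctrl`,
#'   `t_ctrl`, `n_kd`, `t_kd`, `rsc`, `p_raw`, `q_bh`, `call`.
#' @export
spc_differential <- function(x, compartment,
                             conditions = c("control", "kd"), f = 0.5,
                             rsc_threshold = 1.8, alpha = 0.05,
                             use_adjusted = TRUE) {
  ctrl <- pool_replicates(x, conditions[1], compartment)
  kd <- pool_replicates(x, conditions[2], compartment)
  res <- data.frame(
    accession = ctrl$accession,
    compartment = compartment,
    n_ctrl = unname(ctrl$n), t_ctrl = ctrl$t,
    n_kd = unname(kd$n), t_kd = kd$t,
    rsc = unname(compute_rsc(ctrl, kd, f = f)),
    stringsAsFactors = FALSE
  )
  res$p_raw <- fisher_exact_protein(res$n_ctrl, res$t_ctrl,
                                    res$n_kd, res$t_kd)
  res$q_bh <- benjamini_hochberg(res$p_raw)
  call_differential(res, rsc_threshold = rsc_threshold, alpha = alpha,
                    use_adjusted = use_adjusted)
}

#' Differential calls from Rsc and significance
#'
#' A protein is called `up` when `rsc > rsc_threshold` and its significance
#' value is below `alpha`, `down` when `rsc < -rsc_threshold` with the same
#' significance condition, `none` otherwise. Both inequalities are strict.
#' The significance value is the BH-adjusted q (`use_adjusted = TRUE`,
#' default, matching p-values that "were corrected" for multiple testing) or
#' the raw p otherwise.
#'
#' @param results data.frame with columns `rsc`, `p_raw` and (if
#'   `use_adjusted`) `q_bh`.
#' @param rsc_threshold fold-change gate on |Rsc| (default 1.8).
#' @param alpha significance level (default 0.05).
#' @param use_adjusted use `q_bh` rather than `p_raw`.
#' @return `results` with a `call` column (`"up"`, `"down"`, `"none"`).
#' @export
call_differential <- function(results, rsc_threshold = 1.8, alpha = 0.05,
                              use_adjusted = TRUE) {
  sig <- if (use_adjusted) results$q_bh else results$p_raw
  if (is.null(sig))
    stop("required significance column is missing", call. = FALSE)
  results$call <- ifelse(sig < alpha & results$rsc > rsc_threshold, "up",
                  ifelse(sig < alpha & results$rsc < -rsc_threshold, "down",
                         "none"))
  results
}
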