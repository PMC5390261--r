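#' Normalized spectral counts (NSpC)
#'
#' Divides each sample's counts by that sample's total significant spectra,
#' so every column sums to one. Normalized counts are used for correlation
#' and reporting; pooled raw counts are used for Rsc and testing.
#'
#' @param x an [spc_set] or a counts matrix with sample columns.
#' @return numeric matrix of NSpC values, same dimnames as the counts.
#' @export
normalize_counts <- function(x) {
  counts <- if (inherits(x, "spc_set")) x$counts else x
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total spectra: ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  sweep(counts, 2, tot, "/")
}

#' Pool replicate spectral counts for one condition within a compartment
#'
#' Sums each protein's significant spectra over all biological and technical
#' replicates matching the given condition and compartment (the pooled `n`),
#' together with the pooled total `t = sum(n)` used by the Rsc statistic and
#' the Fisher exact test.
#'
#' @param x an [spc_set].
#' @param condition,compartment sample labels to pool.
#' @return list of class `"pooled_counts"`: `accession`, `n` (named integer
#'   vector), `t` (scalar), plus the labels.
#' @export
pool_replicates <- function(x, condition, compartment) {
  stopifnot(inherits(x, "spc_set"))
  sel <- x$samples$condition == condition &
    x$samples$compartment == compartment
  if (!any(sel))
    stop("no samples match condition '", condition, "' in compartment '",
         compartment, "'", call. = FALSE)
  n <- rowSums(x$counts[, sel, drop = FALSE])
  structure(list(accession = rownames(x$counts),
                 n = n, t = sum(n),
                 condition = condition, compartment = compartment),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat(sprintf("pooled_counts: %d proteins, condition '%s', compartment '%s', t = %d\n",
              length(x$n), x$condition, x$compartment, as.integer(x$t)))
  invisible(x)
}

#' Rsc: pseudocount-stabilized log2 spectral-count ratio
#'
#' Computes, per protein, the relative-abundance statistic
#' \deqn{Rsc = \log_2\frac{n_{kd}+f}{n_{ctrl}+f} +
#'       \log_2\frac{t_{ctrl}-n_{ctrl}+f}{t_{kd}-n_{kd}+f}}
#' where `n` are pooled significant spectra for the protein, `t` the pooled
#' totals, and `f > 0` a pseudocount (default 0.5) that keeps the ratio
#' finite for proteins absent in one condition. Positive values mean higher
#' abundance in the knockdown (second) condition.
#'
#' @param pooled_ctrl,pooled_kd [pool_replicates()] results sharing the same
#'   protein index; control (reference) first.
#' @param f pseudocount, must be positive.
#' @return named numeric vector of Rsc values.
#' @examples
#' a <- structure(list(accession = "P1", n = c(P1 = 5), t = 1000),
#'                class = "pooled_counts")
#' b <- structure(list(accession = "P1", n = c(P1 = 20), t = 1000),
#'                class = "pooled_counts")
#' compute_rsc(a, b)  # about 1.92
#' @export
compute_rsc <- function(pooled_ctrl, pooled_kd, f = 0.5) {
  if (f <= 0) stop("pseudocount 'f' must be positive", call. = FALSE)
  if (!identical(pooled_ctrl$accession, pooled_kd$accession))
    stop("pooled structures do not share the same protein index",
         call. = FALSE)
  n1 <- pooled_ctrl$n; t1 <- pooled_ctrl$t
  n2 <- pooled_kd$n;   t2 <- pooled_kd$t
  if (any(n1 > t1) || any(n2 > t2))
    stop("pooled count exceeds pooled total", call. = FALSE)
  log2((n2 + f) / (n1 + f)) + log2((t1 - n1 + f) / (t2 - n2 + f))
}
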