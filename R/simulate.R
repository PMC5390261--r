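#' Simulation configuration
#'
#' Parameters of the synthetic spectral-count generator. The replicate layout
#' mirrors the study design the analysis assumes: two conditions (vector
#' control vs knockdown) observed in three compartments, with 4 biological
#' replicates and 2 technical replicates each, so 8 samples per condition per
#' compartment.
#'
#' Counts follow a negative-binomial model: each protein receives a lognormal
#' baseline abundance (mean `baseline_mean` spectra per sample); for every
#' biological replicate a latent gamma rate with dispersion `dispersion` is
#' drawn, and technical replicates are Poisson draws around that shared latent
#' rate. `dispersion = 0` is the Poisson limit. A `de_fraction` of proteins is
#' truly differential in the knockdown, with |log2 fold changes| uniform
#' between `log2(fold_change_range[1])` and `log2(fold_change_range[2])`,
#' half up and half down. `nuisance_fractions` reserves further proteins as
#' contaminant classes that the curation rules must remove.
#'
#' @param n_proteins number of simulated proteins.
#' @param compartments compartment labels.
#' @param n_biological,n_technical replicate layout per condition.
#' @param baseline_mean expected spectral count per protein per sample.
#' @param abundance_sdlog lognormal spread of per-protein baseline abundance
#'   (0 = all proteins equally abundant).
#' @param dispersion negative-binomial dispersion of biological replicates
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param de_fraction fraction of proteins truly differential.
#' @param fold_change_range range (both > 1) of true fold-change magnitudes.
#' @param nuisance_fractions named numeric vector of contaminant fractions;
#'   allowed names: keratin, no_accession, fragment, uncharacterized,
#'   cdna_like, skeletal_muscle.
#' @param conditions labels for the two conditions, reference first.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 2000L,
                       compartments = c("cell", "secretome", "xenograft"),
                       n_biological = 4L,
                       n_technical = 2L,
                       baseline_mean = 10,
                       abundance_sdlog = 1,
                       dispersion = 0.1,
                       de_fraction = 0.1,
                       fold_change_range = c(2, 8),
                       nuisance_fractions = c(keratin = 0.02,
                                              no_accession = 0.01,
                                              fragment = 0.02,
                                              uncharacterized = 0.02,
                                              cdna_like = 0.01,
                                              skeletal_muscle = 0.01),
                       conditions = c("control", "kd"),
                       seed = 1L) {
  if (n_proteins < 1 || n_biological < 1 || n_technical < 1)
    stop("dimensions must be positive integers", call. = FALSE)
  if (baseline_mean <= 0)
    stop("'baseline_mean' must be positive", call. = FALSE)
  if (dispersion < 0 || abundance_sdlog < 0)
    stop("'dispersion' and 'abundance_sdlog' must be non-negative",
         call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1)
    stop("'de_fraction' must be in [0, 1]", call. = FALSE)
  if (length(fold_change_range) != 2 || any(fold_change_range <= 1) ||
      fold_change_range[1] > fold_change_range[2])
    stop("'fold_change_range' must be an increasing pair of values > 1",
         call. = FALSE)
  if (length(nuisance_fractions)) {
    bad <- setdiff(names(nuisance_fractions), nuisance_classes())
    if (length(bad))
      stop("unknown nuisance class: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(nuisance_fractions < 0 | nuisance_fractions > 1))
      stop("nuisance fractions must be in [0, 1]", call. = FALSE)
  }
  if (de_fraction + sum(nuisance_fractions) > 1)
    stop("de_fraction plus nuisance fractions exceed 1; ",
         "allocations must be disjoint", call. = FALSE)
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stop("'conditions' must be two distinct labels", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 compartments = compartments,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 baseline_mean = baseline_mean,
                 abundance_sdlog = abundance_sdlog,
                 dispersion = dispersion,
                 de_fraction = de_fraction,
                 fold_change_range = fold_change_range,
                 nuisance_fractions = nuisance_fractions,
                 conditions = conditions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

nuisance_classes <- function() {
  c("keratin", "no_accession", "fragment", "uncharacterized",
    "cdna_like", "skeletal_muscle")
}

# Descriptions carrying the keywords each curation rule looks for.
nuisance_description <- function(class, i) {
  switch(class,
    keratin         = sprintf("Keratin, type II cytoskeletal %d", i),
    no_accession    = sprintf("Unassigned spectrum cluster %d", i),
    fragment        = sprintf("Simulated protein %d (Fragment)", i),
    uncharacterized = sprintf("Putative uncharacterized protein C%dorf", i),
    cdna_like       = sprintf("cDNA FLJ%05d, highly similar to protein %d",
                              i, i),
    skeletal_muscle = sprintf("Myosin-%d, skeletal muscle", i),
    stop("unknown nuisance class: ", class, call. = FALSE)
  )
}

#' Simulate a spectral-count study with ground truth
#'
#' Generates a two-condition, multi-compartment spectral-count data set under
#' the model described in [sim_config()], together with protein metadata and a
#' ground-truth table for recovery testing. Identical `config` (including its
#' seed) gives bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements:
#'   \describe{
#'     \item{data}{[spc_set] of counts over all compartments.}
#'     \item{proteins}{data.frame: `accession` (stable row id),
#'       `reported_accession` (blank for the no-accession contaminant class),
#'       `gene`, `description`, `compartments` (`"all"` or a specific label
#'       for compartment-restricted contaminants).}
#'     \item{truth}{data.frame: `accession`, `true_log2_fc`, `is_de`,
#'       `nuisance_class`.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 50, compartments = "cell"))
#' dim(sim$data)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins

  accession <- sprintf("SIM%05d", seq_len(n))
  proteins <- data.frame(
    accession = accession,
    reported_accession = accession,
    gene = sprintf("G%04d", seq_len(n)),
    description = sprintf("Simulated protein %d", seq_len(n)),
    compartments = "all",
    stringsAsFactors = FALSE
  )

  # deterministic stratified allocation: DE block first, then nuisance blocks
  n_de <- round(config$de_fraction * n)
  truth <- data.frame(
    accession = accession,
    true_log2_fc = 0,
    is_de = FALSE,
    nuisance_class = "none",
    stringsAsFactors = FALSE
  )
  if (n_de > 0) {
    lo <- log2(config$fold_change_range[1])
    hi <- log2(config$fold_change_range[2])
    mag <- stats::runif(n_de, lo, hi)
    sgn <- rep_len(c(1, -1), n_de)              # half up, half down
    truth$true_log2_fc[seq_len(n_de)] <- sgn * mag
    truth$is_de[seq_len(n_de)] <- TRUE
  }

  injected <- inject_nuisance_entries(proteins, truth, config)
  proteins <- injected$proteins
  truth <- injected$truth

  # per-protein baseline abundance, lognormal with mean baseline_mean
  sdl <- config$abundance_sdlog
  mu <- stats::rlnorm(n, meanlog = log(config$baseline_mean) - sdl^2 / 2,
                      sdlog = sdl)

  nb <- config$n_biological
  nt <- config$n_technical
  cols <- list(); ids <- character(0)
  for (comp in config$compartments) {
    present <- proteins$compartments == "all" | proteins$compartments == comp
    for (cond in config$conditions) {
      fc <- if (cond == config$conditions[2]) 2^truth$true_log2_fc else 1
      m <- mu * fc * present
      for (b in seq_len(nb)) {
        lambda <- if (config$dispersion > 0) {
          ifelse(m > 0,
                 stats::rgamma(n, shape = 1 / config$dispersion,
                               scale = m * config$dispersion), 0)
        } else m
        for (tch in seq_len(nt)) {
          cols[[length(cols) + 1L]] <- stats::rpois(n, lambda)
          ids <- c(ids, make_sample_id(cond, comp, b, tch))
        }
      }
    }
  }
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(accession, ids)

  list(data = spc_set(counts), proteins = proteins, truth = truth)
}

#' Mark simulated proteins as contaminant (nuisance) entries
#'
#' Converts a deterministic block of null proteins into the contaminant
#' classes that the curation rules are designed to remove: keratins, entries
#' with no accession, peptide fragments, putative uncharacterized proteins,
#' cDNA-like entries, and skeletal-muscle proteins. Exactly
#' `round(fraction * nrow(proteins))` records are assigned per class, taken
#' from the tail of the non-differential pool so allocations are disjoint
#' from the DE block and reproducible. Skeletal-muscle entries are restricted
#' to the xenograft compartment (they model contamination during tumor
#' excision) and carry `compartments = "xenograft"`.
#'
#' @param proteins,truth tables as produced by [simulate_dataset()].
#' @param config a [sim_config()]; only `nuisance_fractions` is used.
#' @return list with updated `proteins` and `truth`.
#' @export
inject_nuisance_entries <- function(proteins, truth, config) {
  fr <- config$nuisance_fractions
  if (!length(fr) || all(fr == 0))
    return(list(proteins = proteins, truth = truth))
  bad <- setdiff(names(fr), nuisance_classes())
  if (length(bad))
    stop("unknown nuisance class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (sum(fr) > 1)
    stop("nuisance fractions sum above 1", call. = FALSE)
  n <- nrow(proteins)
  pool <- which(!truth$is_de & truth$nuisance_class == "none")
  pool <- rev(pool)  # fill from the table's tail, away from the DE block
  for (class in intersect(nuisance_classes(), names(fr))) {
    k <- round(fr[[class]] * n)
    if (k == 0) next
    if (k > length(pool))
      stop("not enough unallocated proteins for nuisance class ", class,
           call. = FALSE)
    idx <- pool[seq_len(k)]
    pool <- pool[-seq_len(k)]
    truth$nuisance_class[idx] <- class
    truth$is_de[idx] <- FALSE
    truth$true_log2_fc[idx] <- 0
    proteins$description[idx] <-
      vapply(seq_along(idx), function(j) nuisance_description(class, j), "")
    if (class == "keratin")
      proteins$gene[idx] <- sprintf("KRT%d", seq_along(idx))
    if (class == "no_accession") {
      # blank the reported accession only; `accession` stays as the stable
      # row id so counts/truth/results remain joinable
      if (is.null(proteins$reported_accession))
        proteins$reported_accession <- proteins$accession
      proteins$reported_accession[idx] <- ""
    }
    if (class == "skeletal_muscle")
      proteins$compartments[idx] <- "xenograft"
  }
  list(proteins = proteins, truth = truth)
}

#' Recovery metrics of differential calls against simulation ground truth
#'
#' Joins a [call_differential()] result table to the simulator's ground truth
#' and summarises recovery: sensitivity (called and truly differential over
#' truly differential), observed FDR (called but truly null over called; 0 by
#' convention when nothing is called), and sign agreement (fraction of
#' correctly called true positives whose call direction matches the sign of
#' the true log2 fold change).
#'
#' @param truth ground-truth table from [simulate_dataset()].
#' @param results differential results with columns `accession` and `call`;
#'   must contain at most one row per accession (subset to one compartment
#'   first).
#' @return list with `n_true_de`, `n_called`, `sensitivity`, `fdr`,
#'   `sign_agreement`.
#' @export
truth_recovery_report <- function(truth, results) {
  if (anyDuplicated(results$accession))
    stop("results contain duplicated accessions; subset to one compartment",
         call. = FALSE)
  m <- merge(truth, results[, c("accession", "call")], by = "accession")
  if (nrow(m) == 0)
    stop("no accessions shared between truth and results", call. = FALSE)
  called <- m$call != "none"
  true_de <- m$is_de
  sens <- if (sum(true_de) == 0) NA_real_ else
    sum(called & true_de) / sum(true_de)
  fdr <- if (sum(called) == 0) 0 else sum(called & !true_de) / sum(called)
  tp <- called & true_de
  sign_ok <- if (sum(tp) == 0) NA_real_ else
    mean((m$call[tp] == "up") == (m$true_log2_fc[tp] > 0))
  list(n_true_de = sum(true_de), n_called = sum(called),
       sensitivity = sens, fdr = fdr, sign_agreement = sign_ok)
}
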