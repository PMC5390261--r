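---
title: "Label-free spectral-count differential analysis: models and methods"
author: "spcdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free spectral-count differential analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcdelta)
```

# The problem

In shotgun proteomics, the number of MS/MS spectra confidently assigned to a
protein — its spectral count (SpC) — is a practical proxy for its abundance.
`spcdelta` implements the complete discovery workflow for comparing two
conditions (here labelled "control" and "kd", for a vector control versus a
stable knockdown) across several sample compartments, typically whole-cell
lysate, secretome (conditioned media), and tumor xenograft tissue, each with
4 biological and 2 technical replicates per condition. The pipeline takes
identification evidence as input and produces curated, annotated lists of
differentially abundant proteins together with the summary artifacts a
discovery study reports: category distributions, sample-correlation
clustering, and exportable gene lists.

# Identification and protein inference

The package does not re-implement search-engine scoring or the
PeptideProphet/ProteinProphet probability models; it consumes their output
abstraction — peptide-spectrum matches (PSMs) with probabilities and decoy
flags — and reproduces the acceptance pipeline applied downstream:

1. **PSM filter** (`filter_psms`): retain PSMs with probability strictly
   above 0.95. The strict inequality is a documented reading of the
   conventional "greater than 95%" acceptance level.
2. **Parsimony inference** (`group_proteins_parsimony`): report the minimal
   set of protein groups explaining all retained peptides.
   Indistinguishable proteins (identical peptide sets) merge into one group;
   proteins subsumed by a selected group are absorbed as members. For up to
   16 distinguishable units and 30 peptides the minimum set cover is found
   exactly by exhaustive subset search (greedy set cover can be one group
   larger on adversarial instances even at this size); larger problems use
   deterministic greedy cover. Ties break lexicographically so results are
   reproducible.
3. **Acceptance** (`accept_protein_groups`): probability strictly above
   0.99 and at least 2 unique peptides; then the decoy FDR, estimated as
   retained decoys over retained targets (the simplest estimator consistent
   with a target-decoy search; the factor-2 variant can be obtained by
   halving `max_fdr`), must not exceed 1%. When it does, the probability
   threshold is raised by the smallest step that restores the bound. The
   probability/FDR interaction is not prescribed by the conventions this
   mirrors; threshold escalation is this package's documented resolution.

Protein probabilities are combined from PSM evidence as
`1 - prod(1 - best probability per peptide)`; a group inherits the maximum
member probability and is decoy only when every member is. These are
deliberately simple conventions — the inputs normally carry
ProteinProphet-style probabilities already, and the combination rule only
matters for synthetic inputs.

# Quantitation: NSpC and Rsc

Two representations of abundance are used for different purposes:

* **NSpC** (`normalize_counts`) divides each sample's counts by the sample's
  total significant spectra, correcting for acquisition depth. NSpC feeds
  correlation, clustering and reporting.
* **Pooled counts** (`pool_replicates`) sum each protein's spectra over all
  replicates of a condition within a compartment (`n`), with `t = sum(n)`.
  Pooling — rather than averaging per replicate — matches the summation the
  spectral-counting literature prescribes and keeps the fold-change
  statistic and the significance test operating on the same quantities.

The fold-change statistic (`compute_rsc`) is the pseudocount-stabilized
log2 ratio of spectral counts:

$$
R_{sc} = \log_2\!\frac{n_{kd}+f}{n_{ctrl}+f}
       + \log_2\!\frac{t_{ctrl}-n_{ctrl}+f}{t_{kd}-n_{kd}+f}
$$

with pseudocount $f = 0.5$ by default. $f$ keeps ratios finite when a
protein is absent from one condition and shrinks extreme ratios at low
counts; 0.5 is the customary choice in the spectral-counting literature and
the exact value used by any given study is rarely recoverable from its
printed tables, so `f` is configurable. Positive $R_{sc}$ means higher
abundance in the knockdown. The statistic is antisymmetric under condition
exchange and strictly monotone in each count.

# Significance testing and calls

Each protein's pooled counts form a 2×2 table
$[[n_{ctrl}, t_{ctrl}-n_{ctrl}], [n_{kd}, t_{kd}-n_{kd}]]$ tested with the
two-sided Fisher exact test (`fisher_exact_protein`). Two-sidedness follows
the minimum-likelihood convention (sum all outcomes no more probable than
the observed one, with the customary $1+10^{-7}$ tie tolerance) — the same
convention as `stats::fisher.test`, against which the implementation is
cross-checked; the in-package implementation shares the hypergeometric
support across proteins with equal margins, which makes whole-proteome
testing and exhaustive validation sweeps fast. Degenerate margins give
$p = 1$.

P-values are corrected with Benjamini–Hochberg (`benjamini_hochberg`,
delegating to `stats::p.adjust`) **within each compartment**, since each
compartment's protein list is reported independently. A protein is called
differential (`call_differential`) when $|R_{sc}| > 1.8$ and its adjusted
q-value is below 0.05; both inequalities strict. Because the criterion's
p-values "were corrected" in the workflow this mirrors, the adjusted value
is the default gate; `use_adjusted = FALSE` switches to raw p-values.

Fisher's test on pooled counts assumes sampling variation only; biological
replicate variability makes it anticonservative on its own. In practice the
fold-change gate dominates the operating characteristics: under the null
simulation below, the joint criterion calls about 0.1% of proteins, far
below the nominal 5%.

# Curation

`apply_exclusion_rules` applies an ordered, auditable rule list
(`default_curation_rules`): non-significant proteins first, then keratins
(ubiquitous sample-handling contaminants; description contains "keratin" or
gene symbol starts with `KRT`), entries without a reported accession,
peptide fragments, putative uncharacterized proteins, cDNA-like entries,
and — in the xenograft compartment only — skeletal-muscle proteins, which
can contaminate excised tumors. The skeletal-muscle keyword is deliberately
the narrow phrase "skeletal muscle": muscle-associated gene products such
as tropomyosins or nebulin are legitimate tumor constituents and must not
be caught by name alone. Each exclusion is attributed to the first matching
rule, so the per-rule ledger sums exactly to the input count; reordering
rules changes attribution but never the retained set. All keywords are
configurable data, not code.

# Reporting

`assign_categories` joins a gene-to-category map (packaged maps are
transcribed from the published tables; unmapped proteins become "Unknown
function"), `category_distribution` converts counts to percentages rounded
half-up to one decimal (matching the convention of the printed figures;
with many categories the rounded percentages can drift from 100 by up to
0.05 points per category), `rank_extremes` reports the most extreme protein
per direction with deterministic gene-symbol tie-breaking, and
`sample_correlation_matrix` + `hierarchical_cluster` produce the
Pearson-correlation heat-map inputs with average-linkage (UPGMA) clustering
on the distance $1-r$. `export_gene_lists` writes deduplicated
one-symbol-per-line files for external network tools (network analysis
itself is out of scope).

The six packaged tables (`curated_fixture`) transcribe the published
curated protein lists verbatim, including context rows whose $|R_{sc}|$
falls below the 1.8 calling threshold; they are reporting inputs and are
never used to validate the calling thresholds. The published percentage
summaries for the down-regulated cellular proteins are consistent with the
reported group size of 18 even though the printed table carries 19 rows;
`category_distribution(total =)` exists precisely so the denominator can be
the reported size.

# The synthetic-data generator

`simulate_dataset` emulates the data structure the analysis assumes, not
the mass spectrometer. Per protein $i$ a baseline abundance $\mu_i$ is
lognormal with mean `baseline_mean` (default 10 spectra per sample, with
`abundance_sdlog = 1` giving the multi-order-of-magnitude abundance spread
typical of spectral counts). For each biological replicate a latent rate is
drawn from a gamma distribution with dispersion 0.1
(variance $= \mu + 0.1\mu^2$, a moderate level between technical-only and
strongly biological variability), and technical replicates are Poisson
around that shared latent rate — so technical duplicates are more similar
to each other than biological replicates, mirroring the 4×2 design.
`dispersion = 0` is the Poisson limit. A fraction `de_fraction = 0.1` of
proteins receives true log2 fold changes uniform in magnitude between
`log2(2)` and `log2(8)`, alternating in sign (half up, half down), applied
in the knockdown in every compartment. Contaminant classes are allocated
deterministically from the tail of the null pool at rates of 1–2% per
class, realistic for keratin/fragment/uncharacterized entries in shotgun
data; skeletal-muscle contaminants carry zero counts outside the xenograft.
All allocations are deterministic given the seed — no rejection sampling —
so identical configurations are bit-identical.

What the generator does **not** emulate: peptide-level sampling and shared
peptides (counts are drawn at the protein level), length bias (no NSAF-type
normalization is attempted), missingness structure beyond sampling zeros,
and compartment-specific regulation (true fold changes are shared across
compartments). Passing recovery tests therefore demonstrate correctness of
the statistical machinery under the stated count model, not performance on
real spectra.

`truth_recovery_report` closes the loop: sensitivity, observed FDR (defined
as 0 when nothing is called), and sign agreement against the ground truth.

# Numerical choices and scale of the validation runs

* Fisher p-values are validated against exhaustive hypergeometric
  enumeration for **every** 2×2 table with total at most 200, enumerated up
  to the row-swap/column-swap/transpose symmetry group (~9×10⁶ canonical
  tables) after property-testing the symmetry invariance itself; agreement
  is within 10⁻⁹ (observed ~5×10⁻¹⁴).
* BH q-values are validated against the direct step-up definition on 1000
  random p-vectors.
* Null calibration uses 10 simulations of 2000 proteins at the default 4×2
  layout; recovery uses 10 simulations of 1000 proteins at
  `baseline_mean = 20` with 8-fold true changes. These sizes give stable
  Monte-Carlo estimates (binomial standard errors below 0.005) while
  keeping the whole validation suite to a few minutes.
* Ties: parsimony leads, extreme ranking, and clustering leaf order all
  break ties deterministically (lexicographic accession / gene symbol /
  input order), so every artifact is byte-reproducible from config + seed.
* Degenerate inputs error early and name the offender: zero-total samples,
  zero-variance samples, counts exceeding totals, malformed sample ids,
  missing protein metadata.

# Known limitations

* Pooled-count Fisher testing ignores biological replicate variance; a
  replicate-aware count model (negative-binomial GLM) is deliberately out
  of scope, as the workflow this package operationalizes tests pooled
  spectra. The fold-change gate mitigates, but does not remove, the
  resulting anticonservatism of the raw p-values.
* The count model is a stand-in: no distributional claim about real
  spectral counts is inherited from the source workflow, which does not
  state one. The negative-binomial choice reflects the overdispersion
  spectral counts commonly show.
* Curation is keyword-based by design; it does not consult contaminant
  databases (cRAP-style lists).
* The pseudocount `f` used by any particular published table is generally
  unrecoverable; small |Rsc| values are therefore not comparable across
  studies at face value.

# Session info

```{r}
sessionInfo()
```
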