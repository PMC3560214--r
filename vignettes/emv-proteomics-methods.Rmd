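---
title: "Methods: proteomic profiling of brain endothelial EMVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic profiling of brain endothelial EMVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emvprofiler)
```

This vignette documents the statistical procedures implemented in
`emvprofiler`, the assumptions behind each, the design decisions that were
genuinely open, and what the synthetic-data generator does and does not
emulate. Nothing here states an empirical result beyond what the package's
tests and acceptance script compute.

## Target-decoy filtering

A composite forward+reverse database search yields peptide-spectrum
matches (PSMs) carrying an ion score, mass errors, a missed-cleavage
count, a charge state (2+, 3+ or 4+), and an independent peptide
probability. A PSM is treated as a decoy if and only if *all* of its
accessions carry the `REV_` prefix: a spectrum matched jointly by a
forward and a reverse entry is evidence for the forward protein, not a
random match.

The false-positive rate of a retained set is estimated as
$\mathrm{FPR} = 2 N_{rev} / (N_{rev} + N_{fwd})$, capped at 1. The factor
2 encodes the composite-search symmetry: a spurious match is equally
likely to land in either database half, so observed reverse hits estimate
half the total false matches.

The gate cascade retains a PSM when ion score $>$ threshold (strict, so a
score of exactly 40 at the default is excluded), $|$parent error$| <$ 0.1
Da, fragment error $<$ 0.2 Da, missed cleavages $\le 1$, and probability
$\ge 0.90$ (inclusive — a probability of exactly 0.90 passes). Parent
errors are signed in the input and compared as absolute values.

`optimize_thresholds()` searches only the ion-score threshold over a
user-supplied grid, holding the other gates fixed; this mirrors how such
cascades are tuned in practice (the secondary gates are instrument-driven
and not usefully searchable). The objective is the number of distinct
(peptide, charge) pairs among retained forward PSMs — peptide counting is
what the FPR ceiling is meant to protect — subject to the PSM-level FPR
not exceeding `fpr_max` (default 0.5%). Ties are broken toward lower
achieved FPR, then toward the higher threshold; both choices are
conservative. If no grid point is feasible, the minimal-FPR point is
returned with `constraint_met = FALSE` and a warning rather than an error,
so a caller can inspect the funnel.

Whether the FPR should be computed over PSMs or over distinct peptides is
ambiguous; both are reported (`fpr`, `fpr_peptides`) and the PSM-level
value is canonical throughout the package.

## MS1 signal fractions

The MS signal of a protein group is the sum of intensities of MS1 ions
whose assigned peptide maps to at least one protein in the group; an ion
counts at most once per group. Ions from shared peptides count *fully*
toward every matching group (no razor assignment): this keeps each group's
signal well defined at the cost of double-counting across groups, which is
why fractions of overlapping groups may sum above 1. The caveat is stated
in the function documentation rather than silently corrected.

The total signal normalizing a fraction includes unassigned ions by
default (`include_unassigned = TRUE`), since the run-level total is the
natural denominator for "fraction of everything the instrument saw"; a
flag restricts the total to identified ions for the alternative
convention.

Replicate-level comparisons with $n = 3$ per condition use
`mann_whitney_exact()`: the null distribution of $U$ is enumerated over
all $\binom{n+m}{n}$ relabelings (capped at a combined 12 observations),
with midranks for ties, and the two-sided p-value is
$\min(1, 2\min(P(U \le u), P(U \ge u)))$. With 3 vs 3 the smallest
attainable two-sided p is 0.1 — an exact test simply cannot produce
p < 0.001 at these sizes, which is why asymptotic p-values at $n = 3$
should not be trusted and are not offered.

## Gel-band molecular-weight concordance

Theoretical molecular weights are computed from sequence with *average*
(not monoisotopic) residue masses plus one water, because the use case is
concordance with SDS-PAGE migration, which reflects average mass. The mass
table is pinned in the package source; agreement with an independent mass
calculator is tested to within 0.01%. Sequences containing the ambiguity
code `X` have undefined mass and are excluded from gel analysis with a
warning.

Band bounds come from the marker lane under the standard log-linear
migration model: $\log_{10}(\mathrm{MW})$ is interpolated linearly in
migration position; edges beyond the outermost markers are clamped to the
nearest marker MW and flagged, since extrapolating a gel calibration is
not defensible.

A protein in a band is *degraded/truncated* when its theoretical MW lies
strictly above the band's upper bound (the intact protein is heavier than
anything that ran there), *potentially modified* when strictly below the
lower bound, and *concordant* otherwise — a MW exactly on a bound is
concordant, because the defining conditions are strict inequalities.
Per-band percentages are signal-weighted and sum to 100 exactly; the
per-band mean and SD of theoretical MW use the sample SD ($n-1$), fitting
the small per-band protein sets. A protein identified in two bands
contributes its within-band signal to each band separately. Since the
aggregation of per-band values into a single lane-level figure can be done
several ways, the package reports both the per-band percentages and a
signal-weighted overall percentage (total degraded signal over total
signal).

## Overlap and over-representation

Venn counts are exact region counts by membership signature for 2 or 3
named sets; identifiers should be pre-normalized with `normalize_ids()`
(uppercase, isoform suffix stripped). A marker *family* counts as found
when any identified accession maps to it, which is how marker catalogs
(e.g. "actins", "tetraspanins") are scored.

`overrep_test()` draws `B` random lists of the same size, uniformly
*without replacement* (a protein list has no duplicates), from a reference
universe, and reports the add-one empirical p-value
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(B+1)$. The add-one rule
keeps p away from zero, which is required for a permutation p-value to be
valid. With the default $B = 100$ the resolution floor is
$1/101 \approx 0.0099$: no empirical scheme with 100 draws can report
p < 0.001, so claims below the floor require raising `B` (the test
converges to the exact hypergeometric tail as $B \to \infty$, which the
test suite checks on small universes at $B = 10{,}000$).

## Surface interactomics

An interaction is a distinct unordered protein pair $\{x, y\}$ with one
endpoint in the EMV surface set and the other in the target-cell surface
set; both orientations of each undirected edge are checked, a pair
supported by several database records counts once, and a self-edge on a
protein present in both sets counts as one interaction with one partnered
protein on each side. Surface localization is an input annotation, never
inferred. The PPI edge list is user-supplied; reported counts are only as
reproducible as the edge list's provenance, which is why the pipeline
report records the input paths.

## Targeted MRM quantification

`extract_transition_signal()` sums trace intensities within
$\pm$ `tolerance_da` of each signature fragment (default $\pm 0.05$ Da,
configurable; the matching window is a design choice since instrument
settings vary). Presence is called when at least `min_fragments_matched`
fragments (default 2) carry non-zero signal — one matching fragment is too
weak an evidence bar, four is brittle to a single noisy channel.
Retention-time gating is deliberately not applied by default: whether a
time window should accompany the mass window depends on acquisition
settings not represented in a flat trace.

Relative quantification divides each sample's raw signal by the median of
the untreated controls. The median uses the *lower-median* convention for
even control counts so the anchor is an actually observed value; with this
convention the control median of the controls' relative levels is exactly
1. The FC5 transition constants (precursor 844.92, peptide
ITWGGDNTFYSNSVK, fragments 534.48, 729.47, 737.89, 1288.44) are pinned in
`fc5_transitions()`.

## The synthetic-data generator

`generate_psm_table()` draws forward and decoy ion scores from two
location-shifted Gumbel distributions (defaults: forward mean 55, SD 12;
decoy mean 12, SD 5). The Gumbel family's heavy right tail mimics
search-engine score behaviour; the decoy moments put the decoy tail where
a small but non-negligible number of decoys crosses low score thresholds.
Probabilities follow a noisy logistic link on the score, except that a
fixed 2% of decoys receives a spuriously high probability — without that
leak the probability gate alone would remove essentially every decoy and
the score-threshold search would have nothing to optimize. Mass errors and
missed cleavages are drawn so a known subset of rows violates each gate.
An optional `prob_range` draws probabilities uniformly instead, for
exercising the probability gate in isolation.

`generate_emv_experiment()` plants:

* a proteome (default 1179 proteins, matching the scale of a deep
  single-cell-type EMV identification list) with family structure, a 35%
  surface fraction, and log-uniform molecular weights on 11–250 kDa;
* log-normal MS1 intensities (multiplicative noise is the norm for MS1),
  with marker-family proteins at a planted fold increase (default 3.3) and
  10% unassigned background ions;
* gel-band assignments in which every band below the top one receives a
  planted `degraded_fraction` (default 0.2) of its signal from proteins
  heavier than its upper bound. The top band has no heavier donors — in a
  real gel nothing can be degraded *into* the heaviest band from above —
  so its planted value is 0 and `$planted$degraded_by_band` records the
  per-band truth;
* a bipartite PPI edge list at a planted density (default 0.01) between
  the EMV surface set and a synthetic target-cell surface list, plus 10%
  decoy edges touching intracellular proteins that a correct interaction
  count must ignore;
* MRM traces with the FC5 fragments spiked (treated samples at 4-fold the
  untreated scale, emulating an RMT-triggered increase in vesicle cargo),
  a strongly spiked reference trace and a blank, with background points
  kept at least 0.2 Da away from every signature fragment.

Identical seed and configuration give byte-identical bundles, and
generation restores the caller's RNG state.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, retention-time structure, correlated intensities within
a protein, shared (degenerate) peptides, protein inference ambiguity, or
any relationship between a protein's abundance and its identifiability.
Passing tests therefore demonstrate that the *computations* are correct
under a clean generative model, not that the pipeline is robust to the
full messiness of real LC-MS/MS data.

## Problem sizes and numerical choices in the test suite

The tests run the generator at 100–2000 proteins and 400–5000 forward
PSMs; parameter-recovery checks use 10 fixed seeds at 2000 proteins
(marker enrichment within ±15% in the mean, per-band degraded percentages
within 5 points of the planted truth) and convergence checks compare mean
absolute errors at two sizes under fixed seeds. Oracles are independent by
construction: exhaustive grid enumeration for the threshold optimizer,
complete enumeration (and `stats::wilcox.test`) for the exact
Mann–Whitney, the hypergeometric tail for the permutation test, a
brute-force double loop for interaction counts, and frozen values from an
independent mass calculator for molecular weights.

## Known limitations

* FPR estimation implements only the composite-search estimator above; no
  q-value or posterior-error modelling, and no rescoring.
* The exact Mann–Whitney is restricted to 12 combined observations;
  larger groups need an approximation this package deliberately omits.
* Ion tables are consumed from the TSV dialect; raw-file ingestion (e.g.
  mzML) is out of scope here, as is any peak picking or deisotoping.
* Gel-band analysis classifies; it does not infer *which* modification
  explains a below-band protein.
* The interactome stage counts edges; it does not predict or score
  interactions.
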