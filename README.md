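# emvprofiler

Downstream analysis of label-free proteomics data from extracellular
microvesicles (EMVs) released by brain endothelial cells. Brain endothelial
cells form the blood–brain barrier; the microvesicles they shed carry
cell-specific protein cargo and are of interest as biomarker sources, as
vehicles of neurovascular cell–cell communication, and as carriers of
receptor-mediated-transcytosis receptors. Characterizing their proteome
raises a series of small, well-defined computational problems that this
package implements as a tested, reusable pipeline:

* **Target-decoy PSM filtering.** Peptide-spectrum matches from a composite
  forward+reverse database search are filtered by a gate cascade (ion score
  > 40, |parent error| < 0.1 Da, fragment error < 0.2 Da, ≤ 1 missed
  cleavage, peptide probability ≥ 0.90). The false-positive rate of the
  retained set is estimated as

  ```
  FPR = 2 · N_rev / (N_rev + N_fwd)
  ```

  and the ion-score threshold is chosen on a grid to maximize the number of
  retained forward peptides subject to FPR ≤ 0.5%.
* **MS1 signal fractions.** The MS signal of a protein group is the sum of
  intensities of ions whose peptide maps into the group; the fraction is
  taken over the total signal of the run (including unassigned ions).
  Small-replicate group comparisons use an exact (complete-enumeration)
  Mann–Whitney U test.
* **Gel-band MW concordance.** Proteins identified in an SDS-PAGE band are
  classified against the band's observed molecular-weight range (calibrated
  log-linearly from the marker lane): theoretical MW above the band means
  likely degraded/truncated, below means potentially post-translationally
  modified. Per-band degraded-signal percentages are signal-weighted.
* **Marker overlap and over-representation.** Venn region counts for 2–3
  identification lists, marker-family overlap against a catalog, and an
  empirical category over-representation test against random same-size
  lists drawn from a reference proteome (add-one permutation p-value).
* **Surface interactomics.** Counting theoretical surface protein–protein
  interactions between EMVs and a target cell type from a PPI edge list.
* **Targeted MRM quantification.** Extraction of signature fragment-ion
  signals within a mass tolerance (pinned constants for the FC5 peptide
  ITWGGDNTFYSNSVK, precursor m/z 844.92, fragments 534.48 / 729.47 /
  737.89 / 1288.44), presence calls, and levels relative to the median
  untreated control.

Because no raw data accompany this kind of experiment, a synthetic-data
generator (`sim_config()`, `generate_psm_table()`,
`generate_emv_experiment()`) builds every fixture with planted ground truth
— score distributions, marker enrichment fold, per-band degraded signal,
bipartite edge density, spiked MRM transitions — so every stage is testable
end to end.

## Worked example

```r
library(emvprofiler)

cfg  <- sim_config(seed = 42, n_forward_psms = 5000, decoy_fraction = 0.5)
psms <- generate_psm_table(cfg)
optimize_thresholds(psms, fpr_max = 0.005, grid = seq(10, 80, by = 5))
#> PSM filter result
#>   retained PSMs: 2905 forward + 0 decoy (FPR 0.0000)
#>   distinct (peptide, charge): 2905 forward + 0 decoy (FPR 0.0000)
#>   ion score > 40, |parent| < 0.1 Da, fragment < 0.2 Da, missed <= 1, p >= 0.9
#>   FPR constraint (<= 0.005): met
```

The optimizer scanned ion-score thresholds 10–80 and settled on 40: lower
thresholds admit enough decoy matches to break the 0.5% FPR ceiling, higher
ones discard forward peptides for no FPR gain.

```r
bundle <- generate_emv_experiment(cfg)
signal_fraction(bundle$ions, bundle$peptide_map,
                bundle$planted$marker_accessions, group_id = "marker_families")
#>          group_id group_signal total_signal  fraction
#> 1 marker_families   2309752076   7831565346 0.2949285

marker_enrichment_estimate(bundle$ions, bundle$peptide_map,
                           bundle$planted$marker_accessions,
                           bundle$proteins$accession)
#> [1] 3.89   # planted fold was 3.3; single-run estimate at n = 1179

s <- count_interactions(bundle$emv_surface, bundle$target_surface, bundle$ppi_edges)
s
#> 393 EMV surface protein(s) could interact with 291 target surface protein(s),
#> forming 1195 theoretical protein-protein interaction(s)
```

Here 29.5% of the total MS1 signal comes from marker-family proteins: each
marker protein carries on average a few-fold more signal than a background
protein (estimated 3.89-fold on this run), and the interactome stage counts
distinct surface protein pairs connected by a PPI edge.

The whole pipeline can also run from files: `write_emv_experiment()`
serializes a bundle, `validate_config()` reads a YAML run configuration and
`run_pipeline()` executes all stages and writes `report.json` plus
per-stage TSVs. A thin command-line wrapper is installed as
`exec/emvprofiler` (`emvprofiler simulate ...`, `emvprofiler run ...`).

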