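test_that("PSM generation honors the forward/decoy count contract", {
  cfg <- sim_config(seed = 1, n_forward_psms = 100, decoy_fraction = 0.5)
  psms <- generate_psm_table(cfg)
  expect_identical(sum(!psms$is_decoy), 100L)
  expect_identical(sum(psms$is_decoy), 100L)
  cfg2 <- sim_config(seed = 1, n_forward_psms = 100, decoy_fraction = 0.25)
  expect_identical(sum(generate_psm_table(cfg2)$is_decoy),
                   as.integer(round(100 * 0.25 / 0.75)))
})

test_that("identical config gives byte-identical outputs; RNG state is untouched", {
  cfg <- sim_config(seed = 5, n_forward_psms = 50, n_proteins = 120)
  set.seed(77); before <- runif(1)
  p1 <- generate_psm_table(cfg)
  p2 <- generate_psm_table(cfg)
  expect_identical(p1, p2)
  f1 <- tempfile(); f2 <- tempfile()
  write_psm_table(p1, f1); write_psm_table(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  b1 <- generate_emv_experiment(cfg)
  b2 <- generate_emv_experiment(cfg)
  expect_identical(b1[setdiff(names(b1), "config")], b2[setdiff(names(b2), "config")])
  set.seed(77); expect_identical(runif(1), before)
})

test_that("experiment bundles survive a write/read cycle", {
  cfg <- sim_config(seed = 3, n_proteins = 100)
  b <- generate_emv_experiment(cfg)
  dir <- tempfile(); write_emv_experiment(b, dir)
  expect_equal(read_fasta(file.path(dir, "proteins.fasta"))$sequence,
               b$proteins$sequence)
  ions <- read_ion_table(file.path(dir, "ions.tsv"))
  expect_equal(ions$intensity, b$ions$intensity, tolerance = 1e-12)
  expect_equal(read_edge_list(file.path(dir, "edges.tsv")), b$ppi_edges)
  expect_setequal(read_catalog(file.path(dir, "marker_catalog.tsv"))$identifier,
                  b$marker_catalog$identifier)
  tr <- read_trace_table(file.path(dir, "traces", "spiked.tsv"))
  expect_equal(tr$mz, b$traces$spiked$mz, tolerance = 1e-12)
})

test_that("invalid config fields are rejected by name", {
  expect_error(sim_config(decoy_fraction = 1), "decoy_fraction")
  expect_error(sim_config(n_forward_psms = 0), "n_forward_psms")
  expect_error(sim_config(marker_enrichment = -1), "marker_enrichment")
  expect_error(sim_config(degraded_fraction = 1.2), "degraded_fraction")
  expect_error(sim_config(edge_density = -0.1), "edge_density")
  expect_error(sim_config(prob_range = c(0.9, 0.5)), "prob_range")
  expect_error(sim_config(decoy_score_mean = 60), "decoy_score_mean")
})

test_that("decoy scores sit below forward scores so filtering prunes decoys harder", {
  cfg <- sim_config(seed = 2, n_forward_psms = 2000, decoy_fraction = 0.5)
  psms <- generate_psm_table(cfg)
  expect_gt(mean(psms$ion_score[!psms$is_decoy]), mean(psms$ion_score[psms$is_decoy]))
  pre <- mean(psms$is_decoy)
  res <- apply_filters(psms, filter_thresholds())
  post <- res$n_rev / (res$n_rev + res$n_fwd)
  expect_lt(post, pre)
  # a known subset violates each individual gate
  expect_gt(sum(abs(psms$parent_error_da) >= 0.1), 0)
  expect_gt(sum(psms$fragment_error_da >= 0.2), 0)
  expect_gt(sum(psms$missed_cleavages > 1), 0)
  expect_gt(sum(psms$probability < 0.9), 0)
})

test_that("probability range override draws probabilities uniformly on the interval", {
  cfg <- sim_config(seed = 4, n_forward_psms = 500, prob_range = c(0.5, 1))
  psms <- generate_psm_table(cfg)
  expect_gte(min(psms$probability), 0.5)
  expect_lte(max(psms$probability), 1)
  expect_gt(mean(psms$probability > 0.9), 0.1)  # uniform, not score-linked
})

test_that("planted-parameter recovery error shrinks as the experiment grows", {
  err_at <- function(n, what) {
    mean(vapply(1:6, function(s) {
      b <- generate_emv_experiment(sim_config(seed = 400 + s, n_proteins = n))
      if (what == "enrichment") {
        est <- marker_enrichment_estimate(b$ions, b$peptide_map,
                                          b$planted$marker_accessions,
                                          b$proteins$accession)
        abs(est - b$config$marker_enrichment)
      } else {
        s_int <- count_interactions(b$emv_surface, b$target_surface, b$ppi_edges)
        n_pairs <- length(b$emv_surface) * length(b$target_surface)
        abs(s_int$n_interactions / n_pairs - b$config$edge_density)
      }
    }, numeric(1)))
  }
  expect_lt(err_at(1200, "enrichment"), err_at(150, "enrichment"))
  expect_lt(err_at(1200, "density"), err_at(150, "density"))
})
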