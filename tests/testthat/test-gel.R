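test_that("MW classification against band bounds uses strict above/below", {
  expect_identical(classify_protein(100, 20, 30), "degraded")
  expect_identical(classify_protein(10, 20, 30), "modified")
  expect_identical(classify_protein(25, 20, 30), "concordant")
  expect_identical(classify_protein(30, 20, 30), "concordant")  # inclusive bound
  expect_identical(classify_protein(20, 20, 30), "concordant")
  expect_error(classify_protein(-1, 20, 30), "positive")
  expect_error(classify_protein(25, 30, 20), "lower < upper")
})

test_that("classification is invariant to Da vs kDa unit choice", {
  set.seed(3)
  mw <- runif(50, 5, 300)
  expect_identical(classify_protein(mw, 20, 30),
                   classify_protein(mw * 1000 / 1000, 20000 / 1000, 30000 / 1000))
})

test_that("band summaries report mean, sample SD and signal-weighted percentages", {
  b <- gel_band(1, 18, 32, data.frame(accession = c("P1", "P2"),
                                      theoretical_mw_kda = c(20, 30),
                                      ms_signal = c(1, 1)))
  s <- band_summary(b)
  expect_equal(s$mean_theoretical_mw_kda, 25)
  expect_equal(s$sd_theoretical_mw_kda, sqrt(50))
  expect_equal(s$pct_signal_degraded, 0)

  b2 <- gel_band(2, 20, 30, data.frame(accession = c("P1", "P2"),
                                       theoretical_mw_kda = c(100, 25),
                                       ms_signal = c(20, 80)))
  expect_equal(band_summary(b2)$pct_signal_degraded, 20)

  b3 <- gel_band(3, 20, 30, data.frame(accession = "P1",
                                       theoretical_mw_kda = 50, ms_signal = 5))
  expect_equal(band_summary(b3)$pct_signal_degraded, 100)

  empty <- band_summary(gel_band(4, 20, 30))
  expect_identical(empty$n_proteins, 0L)
  expect_true(is.na(empty$mean_theoretical_mw_kda))
})

test_that("degraded + modified + concordant percentages sum to 100 exactly", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    b <- gel_band(1, 20, 30, data.frame(
      accession = sprintf("P%d", seq_len(n)),
      theoretical_mw_kda = runif(n, 1, 200),
      ms_signal = runif(n, 0.1, 100)))
    s <- band_summary(b)
    expect_equal(s$pct_signal_degraded + s$pct_signal_modified +
                   s$pct_signal_concordant, 100)
  }
})

test_that("marker-lane calibration interpolates log-linearly and clamps extrapolation", {
  lane <- data.frame(position = c(0, 1), mw_kda = c(100, 10))
  bb <- infer_band_bounds(lane, c(0, 0.5, 1))
  expect_equal(bb$mw_upper_kda, c(100, 10^1.5), tolerance = 1e-12)
  expect_equal(bb$mw_lower_kda, c(10^1.5, 10), tolerance = 1e-12)
  expect_false(any(bb$extrapolated))

  # an edge exactly at a marker position maps to that marker's MW
  lane3 <- data.frame(position = c(0, 0.4, 1), mw_kda = c(200, 50, 8))
  bb3 <- infer_band_bounds(lane3, c(0, 0.4, 1))
  expect_equal(bb3$mw_upper_kda[2], 50, tolerance = 1e-12)

  # clamped beyond the outermost marker, and flagged
  bb4 <- infer_band_bounds(lane, c(-0.2, 0.5, 1.2))
  expect_equal(bb4$mw_upper_kda[1], 100)
  expect_equal(bb4$mw_lower_kda[2], 10)
  expect_true(all(bb4$extrapolated))

  expect_error(infer_band_bounds(lane[1, , drop = FALSE], c(0, 1)), "2 markers")
  expect_error(infer_band_bounds(data.frame(position = c(1, 0), mw_kda = c(10, 100)),
                                 c(0, 1)), "increasing")
})

test_that("lane reports recover planted per-band degraded fractions", {
  cfg <- sim_config(seed = 13, n_proteins = 800, degraded_fraction = 0.25)
  b <- generate_emv_experiment(cfg)
  lane <- gel_lane_report(b$band_assignments, b$band_bounds,
                          b$proteins[c("accession", "theoretical_mw_kda")])
  planted <- b$planted$degraded_by_band
  for (i in seq_len(nrow(lane$bands))) {
    row <- lane$bands[i, ]
    if (row$n_proteins == 0L) next
    expect_equal(row$pct_signal_degraded, 100 * planted[[as.character(row$index)]],
                 tolerance = 1e-6)
  }
  # zero planted degradation yields zero everywhere
  b0 <- generate_emv_experiment(sim_config(seed = 13, n_proteins = 300,
                                           degraded_fraction = 0))
  lane0 <- gel_lane_report(b0$band_assignments, b0$band_bounds,
                           b0$proteins[c("accession", "theoretical_mw_kda")])
  expect_true(all(lane0$bands$pct_signal_degraded[lane0$bands$n_proteins > 0] == 0))
  expect_equal(lane0$overall_pct_degraded, 0)
})
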