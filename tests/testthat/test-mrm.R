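test_that("transition extraction sums trace points inside the tolerance window", {
  trace <- data.frame(mz = c(534.47, 534.60, 729.47), intensity = c(100, 50, 200))
  ts <- fc5_transitions(tolerance_da = 0.05)
  r <- extract_transition_signal(trace, ts)
  expect_equal(r$signals$matched_intensity, c(100, 200, 0, 0))
  expect_equal(r$total, 300)
  expect_equal(r$signals$n_trace_points_matched, c(1L, 1L, 0L, 0L))
  # matched_intensity = 0 iff no points matched (non-zero intensities)
  expect_identical(r$signals$matched_intensity == 0,
                   r$signals$n_trace_points_matched == 0L)

  empty <- extract_transition_signal(data.frame(mz = numeric(0),
                                                intensity = numeric(0)), ts)
  expect_equal(empty$total, 0)
  expect_true(all(empty$signals$matched_intensity == 0))

  two <- data.frame(mz = c(534.46, 534.50), intensity = c(10, 20))
  expect_equal(extract_transition_signal(two, ts)$signals$matched_intensity[1], 30)
})

test_that("transition sets validate and sort their fragments", {
  ts <- transition_set(844.92, "ITWGGDNTFYSNSVK", c(737.89, 534.48, 737.89))
  expect_equal(ts$fragment_mzs, c(534.48, 737.89))
  expect_error(transition_set(844.92, "PEP", numeric(0)), "empty")
  expect_error(transition_set(844.92, "PEP", c(-1, 5)), "positive")
  expect_error(transition_set(844.92, "PEP", 534, tolerance_da = 0), "tolerance")
  fc5 <- fc5_transitions()
  expect_equal(fc5$precursor_mz, 844.92)
  expect_identical(fc5$peptide, "ITWGGDNTFYSNSVK")
  expect_equal(fc5$fragment_mzs, c(534.48, 729.47, 737.89, 1288.44))
})

test_that("extraction is invariant to point order and additive over partitions", {
  set.seed(17)
  trace <- data.frame(mz = runif(200, 400, 1400), intensity = runif(200, 0, 100))
  ts <- fc5_transitions(tolerance_da = 5)  # wide window so matches exist
  full <- extract_transition_signal(trace, ts)$total
  shuffled <- trace[sample.int(nrow(trace)), ]
  expect_equal(extract_transition_signal(shuffled, ts)$total, full)
  part <- extract_transition_signal(trace[1:80, ], ts)$total +
    extract_transition_signal(trace[81:200, ], ts)$total
  expect_equal(part, full)
})

test_that("peptide presence calls count matched fragments", {
  sig <- function(v) data.frame(fragment_mz = seq_along(v), matched_intensity = v,
                                n_trace_points_matched = as.integer(v > 0))
  expect_true(detect_peptide(sig(c(100, 200, 0, 0)), 2))
  expect_false(detect_peptide(sig(c(100, 0, 0, 0)), 2))
  expect_false(detect_peptide(sig(c(0, 0, 0, 0)), 1))
  expect_error(detect_peptide(sig(1), 0), ">= 1")
})

test_that("relative levels anchor to the median untreated control", {
  lv <- relative_level(c(u1 = 10, u2 = 20, u3 = 30, t1 = 60), c("u1", "u2", "u3"))
  expect_equal(lv$relative_to_median_control[lv$sample_id == "t1"], 3)
  expect_equal(lv$relative_to_median_control[lv$sample_id == "u2"], 1)
  # control median of the controls' relative levels is exactly 1 (odd count)
  ctrl <- lv$relative_to_median_control[lv$is_control]
  expect_identical(sort(ctrl)[2], 1)
  # even control count: lower-median convention anchors on an observed value
  lv2 <- relative_level(c(a = 10, b = 20, c = 40, d = 80), c("a", "b", "c", "d"))
  expect_equal(lv2$relative_to_median_control[lv2$sample_id == "b"], 1)
  # single control
  lv3 <- relative_level(c(a = 5, b = 15), "a")
  expect_equal(lv3$relative_to_median_control, c(1, 3))

  expect_error(relative_level(c(a = 1), character(0)), "control")
  expect_error(relative_level(c(a = 0, b = 1), "a"), "positive")
  expect_error(relative_level(c(a = 1), "z"), "not in samples")
})

test_that("spiked traces are detected and blanks are not, across seeds", {
  for (s in 1:5) {
    b <- generate_emv_experiment(sim_config(seed = 300 + s, n_proteins = 150))
    ts <- fc5_transitions()
    expect_true(detect_peptide(extract_transition_signal(b$traces$spiked, ts)$signals))
    expect_false(detect_peptide(extract_transition_signal(b$traces$blank, ts)$signals))
    totals <- vapply(b$traces[b$control_ids], function(tr)
      extract_transition_signal(tr, ts)$total, numeric(1))
    lv <- relative_level(totals, b$control_ids)
    expect_equal(sort(lv$relative_to_median_control)[2], 1)
  }
})
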