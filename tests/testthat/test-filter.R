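test_that("the target-decoy FPR estimator matches hand arithmetic and caps at 1", {
  expect_equal(compute_fpr(1, 399), 0.005)
  expect_equal(compute_fpr(0, 100), 0)
  expect_equal(compute_fpr(5, 5), 1)      # 2*5/10, cap boundary
  expect_equal(compute_fpr(9, 1), 1)      # capped
  expect_error(compute_fpr(0, 0), "no retained peptides")
  expect_error(compute_fpr(-1, 5), "non-negative")
})

test_that("gate boundaries: score strictly above, probability inclusive", {
  at_score <- make_psms(score = 40, decoy = FALSE)
  expect_identical(nrow(apply_filters(at_score)$retained), 0L)
  above <- make_psms(score = 40.0001, decoy = FALSE)
  expect_identical(nrow(apply_filters(above)$retained), 1L)

  at_prob <- make_psms(score = 50, decoy = FALSE, prob = 0.90)
  expect_identical(nrow(apply_filters(at_prob)$retained), 1L)
  below_prob <- make_psms(score = 50, decoy = FALSE, prob = 0.8999)
  expect_identical(nrow(apply_filters(below_prob)$retained), 0L)

  # parent error is compared as an absolute value, strictly
  signed <- make_psms(score = rep(50, 3), decoy = rep(FALSE, 3),
                      parent = c(-0.09, 0.1, -0.11))
  expect_identical(apply_filters(signed)$n_fwd, 1L)
})

test_that("two forward plus two decoy survivors give FPR 1", {
  psms <- make_psms(score = rep(60, 4), decoy = c(FALSE, FALSE, TRUE, TRUE))
  res <- apply_filters(psms)
  expect_identical(res$n_fwd, 2L)
  expect_identical(res$n_rev, 2L)
  expect_equal(res$fpr, 1)
  expect_equal(res$fpr, compute_fpr(res$n_rev, res$n_fwd))
  expect_error(apply_filters(psms[0, ]), "empty")
})

test_that("tightening any single threshold never adds a PSM (anti-monotonicity)", {
  for (seed in 1:5) {
    psms <- random_psms(120, seed)
    base <- filter_thresholds()
    retained0 <- apply_filters(psms, base)$retained$spectrum_id
    tighter <- list(
      filter_thresholds(min_ion_score = 50),
      filter_thresholds(max_parent_error_da = 0.05),
      filter_thresholds(max_fragment_error_da = 0.1),
      filter_thresholds(max_missed_cleavages = 0L),
      filter_thresholds(min_probability = 0.95))
    for (t in tighter) {
      retained1 <- apply_filters(psms, t)$retained$spectrum_id
      expect_true(all(retained1 %in% retained0))
    }
  }
})

test_that("threshold optimization equals exhaustive grid enumeration", {
  grid <- c(10, 20, 30, 40)
  for (seed in 1:20) {
    psms <- random_psms(100, seed)
    want <- oracle_optimize(psms, fpr_max = 0.25, grid = grid)
    if (is.null(want)) {
      expect_error(optimize_thresholds(psms, fpr_max = 0.25, grid = grid),
                   "no grid point")
      next
    }
    got <- suppressWarnings(optimize_thresholds(psms, fpr_max = 0.25, grid = grid))
    expect_equal(got$thresholds_used$min_ion_score, want$s)
    expect_equal(got$n_peptides_fwd, want$n_pep)
    expect_equal(got$n_fwd, want$n_fwd)
    expect_equal(got$n_rev, want$n_rev)
    expect_equal(got$fpr, want$fpr)
    expect_identical(got$constraint_met, want$constraint_met)
  }
})

test_that("optimization flags constraint failure and returns the minimal-FPR point", {
  # all survivors decoy at every grid point -> FPR 1 everywhere
  psms <- make_psms(score = rep(60, 4), decoy = rep(TRUE, 4))
  expect_warning(res <- optimize_thresholds(psms, fpr_max = 0.005, grid = c(10, 20)),
                 "no score threshold")
  expect_false(res$constraint_met)
  expect_equal(res$fpr, 1)
  expect_error(optimize_thresholds(make_psms(), grid = numeric(0)), "empty")
})

test_that("a trivially clean table retains everything at FPR 0", {
  psms <- make_psms(score = rep(50, 5), decoy = rep(FALSE, 5))
  res <- optimize_thresholds(psms, fpr_max = 0.005, grid = 40)
  expect_identical(res$n_fwd, 5L)
  expect_equal(res$fpr, 0)
})

test_that("subsample FPR deviation shrinks with table size", {
  loose <- filter_thresholds(min_ion_score = 10)
  dev_at <- function(n) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(seed = 100 + s, n_forward_psms = n, decoy_fraction = 0.5)
      psms <- generate_psm_table(cfg)
      full <- apply_filters(psms, loose)$fpr
      set.seed(1000 + s)
      half <- psms[sample.int(nrow(psms), nrow(psms) %/% 2), ]
      abs(apply_filters(half, loose)$fpr - full)
    }, numeric(1)))
  }
  expect_lt(dev_at(4000), dev_at(400))
})
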