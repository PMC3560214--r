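test_that("venn region counts follow set arithmetic", {
  v <- venn(list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "d", "e")))
  expect_identical(v[["A"]], 1L)
  expect_identical(v[["B"]], 0L)
  expect_identical(v[["C"]], 1L)
  expect_identical(v[["A&B"]], 1L)
  expect_identical(v[["A&C"]], 0L)
  expect_identical(v[["B&C"]], 1L)
  expect_identical(v[["A&B&C"]], 1L)
  expect_identical(sum(v), 5L)  # |A u B u C|

  same <- venn(list(X = letters[1:4], Y = letters[1:4]))
  expect_identical(same[["X&Y"]], 4L)
  expect_identical(same[["X"]] + same[["Y"]], 0L)

  disj <- venn(list(X = c("a", "b"), Y = c("c"), Z = c("d")))
  expect_true(all(disj[grepl("&", names(disj))] == 0L))

  expect_error(venn(list(A = "a", B = "b", C = "c", D = "d")), "2 or 3")
  expect_error(venn(list("a", "b")), "named")
})

test_that("venn counts are invariant under set order up to relabeling", {
  set.seed(31)
  sets <- list(A = sample(letters, 10), B = sample(letters, 12), C = sample(letters, 8))
  v1 <- venn(sets)
  v2 <- venn(sets[c("C", "A", "B")])
  relabel <- function(sig) paste(sort(strsplit(sig, "&", fixed = TRUE)[[1]]), collapse = "&")
  expect_mapequal(setNames(as.integer(v1), vapply(names(v1), relabel, "")),
                  setNames(as.integer(v2), vapply(names(v2), relabel, "")))
})

test_that("marker families count as found when any member is identified", {
  fam <- data.frame(accession = c("P1", "P2", "P3"),
                    family_symbol = c("ACT", "ACT", "TUB"), stringsAsFactors = FALSE)
  ov <- marker_overlap(c("P1"), c("ACT", "TUB"), fam)
  expect_identical(ov$n_found, 1L)
  expect_identical(ov$n_total, 2L)
  expect_identical(ov$families_found, "ACT")
  expect_identical(marker_overlap(character(0), c("ACT", "TUB"), fam)$n_found, 0L)
  all_found <- marker_overlap(c("P1", "P3"), c("ACT", "TUB"), fam)
  expect_identical(all_found$n_found, all_found$n_total)
})

test_that("identifier normalization uppercases and strips isoform suffixes", {
  expect_identical(normalize_ids(c("p60709-2", "P60709", "q9y6w5-1")),
                   c("P60709", "P60709", "Q9Y6W5"))
})

test_that("permutation over-representation p matches the hypergeometric tail", {
  universe <- sprintf("U%02d", 1:10)
  annotations <- data.frame(accession = universe[1:5], category = "cat",
                            stringsAsFactors = FALSE)
  r <- overrep_test(universe[1:3], universe, annotations, "cat",
                    B = 10000, seed = 1)
  # exact tail: P(all 3 sampled in the 5-member category) = C(5,3)/C(10,3)
  expect_lt(abs(r$p_empirical - choose(5, 3) / choose(10, 3)), 0.01)
  expect_identical(r$observed, 3L)
})

test_that("empirical p respects its resolution floor and add-one rule", {
  universe <- sprintf("U%02d", 1:20)
  annotations <- data.frame(accession = universe[1:10], category = "cat",
                            stringsAsFactors = FALSE)
  # observed 0 with a populated category: every null count is >= 0 -> p = 1
  r0 <- overrep_test(universe[11:13], universe, annotations, "cat", B = 50, seed = 2)
  expect_identical(r0$observed, 0L)
  expect_equal(r0$p_empirical, 1)
  # a list that beats every null at B = 100 bottoms out at 1/101
  r1 <- overrep_test(universe[1:10], universe, annotations, "cat", B = 100, seed = 3)
  expect_equal(r1$p_empirical, 1 / 101)
  expect_gte(r1$p_empirical, 1 / (r1$B + 1))
  expect_identical(r1$p_empirical,
                   (1 + sum(r1$null_counts >= r1$observed)) / (r1$B + 1))

  expect_error(overrep_test(sprintf("X%d", 1:30), universe, annotations, "cat"),
               "larger than")
  expect_error(overrep_test(universe[1:2], universe, annotations, "nope"),
               "absent")
})

test_that("resampling is reproducible under a fixed seed and leaves the RNG state alone", {
  universe <- sprintf("U%02d", 1:20)
  annotations <- data.frame(accession = universe[1:10], category = "cat",
                            stringsAsFactors = FALSE)
  set.seed(99); before <- runif(1)
  r1 <- overrep_test(universe[1:5], universe, annotations, "cat", B = 20, seed = 7)
  r2 <- overrep_test(universe[1:5], universe, annotations, "cat", B = 20, seed = 7)
  expect_identical(r1$null_counts, r2$null_counts)
  set.seed(99); expect_identical(runif(1), before)
})
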