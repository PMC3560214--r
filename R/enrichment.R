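# Catalog overlap and over-representation: Venn region counts for 2-3
# protein lists, marker-family overlap against a reference catalog, and an
# empirical (resampling) test of category over-representation against
# random lists drawn from a reference proteome.

#' Normalize protein identifiers
#'
#' Uppercases and strips isoform suffixes (everything after the first
#' `-`), so `p60709-2` and `P60709` collapse to the same identifier before
#' set comparisons.
#'
#' @param ids Character vector of identifiers.
#' @return Normalized character vector.
#' @export
normalize_ids <- function(ids) sub("-.*$", "", toupper(ids))

#' Venn region counts for two or three sets
#'
#' Exact counts of every exclusive membership region. Identifiers are
#' assumed pre-normalized (see [normalize_ids()]).
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector keyed by membership signature
#'   (`"A"`, `"A&B"`, ... using the supplied set names), of class
#'   `venn_counts`. The counts sum to the size of the union.
#' @export
venn <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list", call. = FALSE)
  k <- length(sets)
  if (k < 2L || k > 3L) stop("venn supports 2 or 3 sets only", call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  sig <- apply(membership, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(size) {
    utils::combn(names(sets), size, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  structure(counts, class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn region counts (", sum(x), " in union):\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-12s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Overlap between identified proteins and a marker-family catalog
#'
#' A marker family (e.g. `ACT` for actins) counts as found when at least
#' one identified accession maps to it.
#'
#' @param identified Character vector of identified accessions.
#' @param marker_families Character vector of marker family symbols in the
#'   catalog.
#' @param family_map Data frame with columns `accession`, `family_symbol`.
#' @return List with `n_found`, `n_total`, and `families_found`.
#' @export
marker_overlap <- function(identified, marker_families, family_map) {
  stopifnot(all(c("accession", "family_symbol") %in% names(family_map)))
  marker_families <- unique(marker_families)
  fams_identified <- unique(family_map$family_symbol[family_map$accession %in% identified])
  found <- sort(intersect(marker_families, fams_identified))
  list(n_found = length(found), n_total = length(marker_families),
       families_found = found)
}

#' Permutation over-representation test for a category
#'
#' Compares the number of category members in a protein list to its null
#' distribution under `B` random lists of the same size drawn uniformly
#' without replacement from a reference proteome. The empirical p-value
#' uses the add-one rule `p = (1 + #[null >= observed]) / (B + 1)`, so the
#' smallest attainable p is `1/(B + 1)` (about 0.0099 at the default
#' B = 100) -- a resolution floor that no permutation scheme with B draws
#' can beat.
#'
#' @param list_proteins Character vector, the protein list under test.
#' @param universe Character vector of reference accessions to sample from;
#'   must be at least as large as `list_proteins`.
#' @param annotations Data frame with columns `accession`, `category`
#'   (flat tags; one row per protein-category link).
#' @param category The category tag to test.
#' @param B Number of random lists.
#' @param seed Integer seed for reproducible resampling.
#' @return Object of class `overrep_result`: `category`, `observed`,
#'   `null_counts` (length B), `p_empirical`, `B`.
#' @export
overrep_test <- function(list_proteins, universe, annotations, category,
                         B = 100L, seed = 1L) {
  stopifnot(all(c("accession", "category") %in% names(annotations)))
  list_proteins <- unique(list_proteins)
  universe <- unique(universe)
  if (length(list_proteins) > length(universe))
    stop("protein list is larger than the reference universe", call. = FALSE)
  if (!category %in% annotations$category)
    stop(sprintf("category '%s' absent from the annotation table", category),
         call. = FALSE)
  members <- unique(annotations$accession[annotations$category == category])
  observed <- sum(list_proteins %in% members)
  n <- length(list_proteins)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_counts <- vapply(seq_len(B), function(i) {
    sum(sample(universe, n, replace = FALSE) %in% members)
  }, integer(1))
  structure(list(category = category, observed = observed,
                 null_counts = null_counts,
                 p_empirical = (1 + sum(null_counts >= observed)) / (B + 1),
                 B = as.integer(B)),
            class = "overrep_result")
}

#' @export
print.overrep_result <- function(x, ...) {
  cat(sprintf("Over-representation of '%s': observed %d, null mean %.2f, empirical p = %.4g (B = %d, floor %.4g)\n",
              x$category, x$observed, mean(x$null_counts), x$p_empirical,
              x$B, 1 / (x$B + 1)))
  invisible(x)
}
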