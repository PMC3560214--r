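# MS1 signal-fraction quantification: map ion intensities to protein groups
# through their peptide assignments, express group signal as a fraction of
# the total signal of the run, and compare small groups of fractions with an
# exact Mann-Whitney test.

.assigned_accessions <- function(ions, peptide_to_proteins) {
  assigned <- !is.na(ions$peptide) & nzchar(ions$peptide)
  missing <- setdiff(unique(ions$peptide[assigned]), peptide_to_proteins$peptide)
  if (length(missing) > 0L) {
    stop(sprintf("peptide(s) absent from the peptide-to-protein mapping: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  split(peptide_to_proteins$accession, peptide_to_proteins$peptide)
}

#' Summed MS1 signal of a protein group
#'
#' The MS signal of a group of proteins is the sum of intensities of ions
#' whose assigned peptide maps to at least one accession in the group. An
#' ion is counted at most once per group; an ion whose (shared) peptide maps
#' to several groups contributes fully to each of them (no razor splitting),
#' so group signals are well defined but may double-count across groups.
#'
#' @param ions Ion-feature data frame (see [read_ion_table()]).
#' @param peptide_to_proteins Data frame with columns `peptide`, `accession`
#'   covering every assigned peptide present in `ions`.
#' @param group Character vector of accessions.
#' @return Summed intensity (numeric scalar).
#' @export
group_signal <- function(ions, peptide_to_proteins, group) {
  if (length(group) == 0L) return(0)
  map <- .assigned_accessions(ions, peptide_to_proteins)
  assigned <- !is.na(ions$peptide) & nzchar(ions$peptide)
  in_group <- vapply(ions$peptide, function(p) {
    !is.na(p) && nzchar(p) && any(map[[p]] %in% group)
  }, logical(1), USE.NAMES = FALSE)
  sum(ions$intensity[assigned & in_group])
}

#' MS1 signal fraction of a protein group
#'
#' Fraction of the total MS signal of the run attributable to a protein
#' group. By default the total sums *all* ions, including features never
#' assigned to an identified peptide; set `include_unassigned = FALSE` to
#' normalize over identified ions only.
#'
#' @inheritParams group_signal
#' @param group_id Label for the group in the report.
#' @param include_unassigned Include unassigned ions in the total signal.
#' @return One-row data frame of class `signal_report` with columns
#'   `group_id`, `group_signal`, `total_signal`, `fraction`.
#' @export
signal_fraction <- function(ions, peptide_to_proteins, group,
                            group_id = "group", include_unassigned = TRUE) {
  assigned <- !is.na(ions$peptide) & nzchar(ions$peptide)
  total <- if (include_unassigned) sum(ions$intensity) else sum(ions$intensity[assigned])
  if (!is.finite(total) || total <= 0) stop("total MS signal is zero", call. = FALSE)
  gs <- group_signal(ions, peptide_to_proteins, group)
  out <- data.frame(group_id = group_id, group_signal = gs,
                    total_signal = total, fraction = gs / total,
                    stringsAsFactors = FALSE)
  class(out) <- c("signal_report", "data.frame")
  out
}

#' Group protein entries by family symbol
#'
#' Families are the grouping unit for marker catalogs (e.g. all actins share
#' the family symbol `ACT`): this partitions accessions by their
#' `family_symbol`.
#'
#' @param proteins Data frame with columns `accession` and `family_symbol`.
#' @return Named list mapping family symbol to a character vector of
#'   accessions.
#' @export
group_by_family <- function(proteins) {
  if (nrow(proteins) == 0L) return(stats::setNames(list(), character(0)))
  if (any(!nzchar(proteins$family_symbol)))
    stop("family_symbol must be non-empty for every protein", call. = FALSE)
  lapply(split(proteins$accession, proteins$family_symbol), unique)
}

#' Exact Mann-Whitney U test by complete enumeration
#'
#' For the very small group sizes typical of replicate-level MS comparisons
#' (n = 3 per condition) asymptotic p-values are meaningless, so the null
#' distribution of U is enumerated over all `choose(n + m, n)` relabelings
#' of the pooled observations. Ties are handled with midranks. The
#' two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b Numeric vectors (combined length at most 12).
#' @return List with elements `U` (statistic for sample `a`) and
#'   `p_two_sided`.
#' @export
mann_whitney_exact <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(a); m <- length(b); N <- n + m
  if (N > 12L)
    stop("combined sample size exceeds the exact-enumeration regime (12); use a normal approximation",
         call. = FALSE)
  r <- rank(c(a, b))  # midranks
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  u_null <- utils::combn(N, n, u_of)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_null <= u_obs + eps), mean(u_null >= u_obs - eps)))
  list(U = u_obs, p_two_sided = p)
}

#' Estimate the marker-family signal enrichment factor
#'
#' Ratio of the mean per-protein MS signal of marker-family proteins to that
#' of all other proteins, the pipeline's estimator of the planted
#' `marker_enrichment` fold change of the synthetic-data generator. Proteins
#' with no assigned ions contribute zero signal but still count toward their
#' class size.
#'
#' @inheritParams group_signal
#' @param marker_accessions Accessions belonging to marker families.
#' @param all_accessions All protein accessions in the experiment.
#' @return Estimated fold enrichment (numeric scalar).
#' @export
marker_enrichment_estimate <- function(ions, peptide_to_proteins,
                                       marker_accessions, all_accessions) {
  marker_accessions <- intersect(marker_accessions, all_accessions)
  other <- setdiff(all_accessions, marker_accessions)
  if (length(marker_accessions) == 0L || length(other) == 0L)
    stop("both marker and non-marker proteins are required", call. = FALSE)
  # per-protein totals in one pass: ion intensity credited to every mapped protein
  assigned <- !is.na(ions$peptide) & nzchar(ions$peptide)
  map <- .assigned_accessions(ions, peptide_to_proteins)
  ii <- ions[assigned, , drop = FALSE]
  acc_per_ion <- map[ii$peptide]
  totals <- tapply(rep(ii$intensity, lengths(acc_per_ion)), unlist(acc_per_ion), sum)
  sig <- function(accs) sum(totals[intersect(names(totals), accs)])
  (sig(marker_accessions) / length(marker_accessions)) / (sig(other) / length(other))
}
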