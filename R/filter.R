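# Target-decoy PSM filtering: the estimator FPR = 2*Nrev / (Nrev + Nfwd)
# applied to the set retained by a cascade of score/tolerance gates, and a
# constrained search for the ion-score threshold that maximizes retained
# forward peptides subject to an FPR ceiling.

#' Filter thresholds for the PSM gate cascade
#'
#' Defaults reproduce the published cascade: ion score strictly above 40,
#' absolute parent-ion mass error below 0.1 Da, fragment mass error below
#' 0.2 Da, at most one missed cleavage, peptide probability at least 0.90,
#' and a target false-positive-rate ceiling of 0.5%.
#'
#' @param min_ion_score Strict lower bound on the ion score.
#' @param max_parent_error_da Strict upper bound on |parent mass error| (Da).
#' @param max_fragment_error_da Strict upper bound on fragment mass error (Da).
#' @param max_missed_cleavages Inclusive upper bound on missed cleavages.
#' @param min_probability Inclusive lower bound on peptide probability.
#' @param fpr_max Ceiling on the target-decoy FPR (proportion, not percent).
#' @return Object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_ion_score = 40,
                              max_parent_error_da = 0.1,
                              max_fragment_error_da = 0.2,
                              max_missed_cleavages = 1L,
                              min_probability = 0.90,
                              fpr_max = 0.005) {
  if (!is.numeric(max_parent_error_da) || max_parent_error_da <= 0)
    stop("max_parent_error_da must be > 0", call. = FALSE)
  if (!is.numeric(max_fragment_error_da) || max_fragment_error_da <= 0)
    stop("max_fragment_error_da must be > 0", call. = FALSE)
  if (max_missed_cleavages < 0 || max_missed_cleavages != round(max_missed_cleavages))
    stop("max_missed_cleavages must be a non-negative integer", call. = FALSE)
  if (min_probability < 0 || min_probability > 1)
    stop("min_probability must be in [0, 1]", call. = FALSE)
  if (fpr_max <= 0 || fpr_max > 1)
    stop("fpr_max must be in (0, 1]", call. = FALSE)
  structure(list(min_ion_score = min_ion_score,
                 max_parent_error_da = max_parent_error_da,
                 max_fragment_error_da = max_fragment_error_da,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_probability = min_probability,
                 fpr_max = fpr_max),
            class = "filter_thresholds")
}

#' Target-decoy false-positive rate
#'
#' The composite forward+reverse database estimator: `2 * n_rev /
#' (n_rev + n_fwd)`, capped at 1. The factor 2 reflects that a random match
#' is equally likely to land in either half of the composite database, so
#' the observed reverse hits estimate half of the false forward hits.
#'
#' @param n_rev Number of retained reverse-database (decoy) identifications.
#' @param n_fwd Number of retained forward-database identifications.
#' @return FPR as a proportion in \[0, 1\].
#' @examples
#' compute_fpr(1, 399)  # 0.005
#' @export
compute_fpr <- function(n_rev, n_fwd) {
  if (length(n_rev) != 1L || length(n_fwd) != 1L || n_rev < 0 || n_fwd < 0 ||
      n_rev != round(n_rev) || n_fwd != round(n_fwd))
    stop("n_rev and n_fwd must be single non-negative integers", call. = FALSE)
  if (n_rev + n_fwd == 0) stop("no retained peptides", call. = FALSE)
  min(1, 2 * n_rev / (n_rev + n_fwd))
}

.psm_pass <- function(psms, t) {
  psms$ion_score > t$min_ion_score &
    abs(psms$parent_error_da) < t$max_parent_error_da &
    psms$fragment_error_da < t$max_fragment_error_da &
    psms$missed_cleavages <= t$max_missed_cleavages &
    psms$probability >= t$min_probability
}

.distinct_peptides <- function(psms) {
  length(unique(paste(psms$peptide, psms$charge)))
}

#' Apply the PSM filter cascade
#'
#' Retains PSMs satisfying every gate (score strictly above threshold,
#' strict tolerance bounds, inclusive missed-cleavage and probability
#' bounds) and computes the target-decoy FPR on the retained set, both at
#' PSM level (canonical) and over distinct (peptide, charge) pairs.
#'
#' @param psms PSM data frame (see [read_psm_table()]); must be non-empty.
#' @param thresholds A [filter_thresholds()] object.
#' @return Object of class `filter_result`: the retained data frame, counts
#'   `n_fwd`/`n_rev` (PSM level), `fpr`, distinct-peptide counts and
#'   peptide-level FPR, and the thresholds used.
#' @export
apply_filters <- function(psms, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!is.data.frame(psms) || nrow(psms) == 0L)
    stop("empty PSM input", call. = FALSE)
  retained <- psms[.psm_pass(psms, thresholds), , drop = FALSE]
  rownames(retained) <- NULL
  n_fwd <- sum(!retained$is_decoy)
  n_rev <- sum(retained$is_decoy)
  fwd <- retained[!retained$is_decoy, , drop = FALSE]
  rev <- retained[retained$is_decoy, , drop = FALSE]
  n_pep_fwd <- .distinct_peptides(fwd)
  n_pep_rev <- .distinct_peptides(rev)
  structure(list(
    retained = retained,
    n_fwd = n_fwd,
    n_rev = n_rev,
    fpr = if (n_fwd + n_rev > 0) compute_fpr(n_rev, n_fwd) else NA_real_,
    n_peptides_fwd = n_pep_fwd,
    n_peptides_rev = n_pep_rev,
    fpr_peptides = if (n_pep_fwd + n_pep_rev > 0) compute_fpr(n_pep_rev, n_pep_fwd)
                   else NA_real_,
    thresholds_used = thresholds
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("PSM filter result\n")
  cat(sprintf("  retained PSMs: %d forward + %d decoy (FPR %.4f)\n",
              x$n_fwd, x$n_rev, x$fpr))
  cat(sprintf("  distinct (peptide, charge): %d forward + %d decoy (FPR %.4f)\n",
              x$n_peptides_fwd, x$n_peptides_rev, x$fpr_peptides))
  cat(sprintf("  ion score > %g, |parent| < %g Da, fragment < %g Da, ",
              x$thresholds_used$min_ion_score,
              x$thresholds_used$max_parent_error_da,
              x$thresholds_used$max_fragment_error_da))
  cat(sprintf("missed <= %d, p >= %g\n",
              x$thresholds_used$max_missed_cleavages,
              x$thresholds_used$min_probability))
  if (!is.null(x$constraint_met))
    cat(sprintf("  FPR constraint (<= %g): %s\n", x$thresholds_used$fpr_max,
                if (x$constraint_met) "met" else "NOT met"))
  invisible(x)
}

#' Optimize the ion-score threshold under an FPR constraint
#'
#' Searches a grid of ion-score thresholds (all other gates held at their
#' defaults or at the supplied values) for the one that maximizes the number
#' of retained distinct forward (peptide, charge) pairs among grid points
#' whose PSM-level FPR does not exceed `fpr_max`. Ties are broken toward
#' lower achieved FPR, then toward the higher (more conservative) score
#' threshold. If no grid point satisfies the constraint, the point with the
#' smallest achieved FPR is returned and `constraint_met` is `FALSE`.
#'
#' @param psms PSM data frame; must be non-empty.
#' @param fpr_max FPR ceiling (proportion).
#' @param grid Numeric vector of candidate ion-score thresholds.
#' @param thresholds Base thresholds for the fixed gates.
#' @return A `filter_result` with extra fields `constraint_met`, `grid`, and
#'   `grid_summary` (per-candidate forward-peptide counts and FPRs).
#' @export
optimize_thresholds <- function(psms, fpr_max = 0.005,
                                grid = seq(10, 80, by = 5),
                                thresholds = filter_thresholds()) {
  if (length(grid) == 0L) stop("empty score-threshold grid", call. = FALSE)
  if (!is.data.frame(psms) || nrow(psms) == 0L)
    stop("empty PSM input", call. = FALSE)
  grid <- sort(unique(grid))
  res <- lapply(grid, function(s) {
    t <- thresholds
    t$min_ion_score <- s
    t$fpr_max <- fpr_max
    apply_filters(psms, t)
  })
  summary_df <- data.frame(
    min_ion_score = grid,
    n_peptides_fwd = vapply(res, `[[`, numeric(1), "n_peptides_fwd"),
    n_fwd = vapply(res, `[[`, numeric(1), "n_fwd"),
    n_rev = vapply(res, `[[`, numeric(1), "n_rev"),
    fpr = vapply(res, `[[`, numeric(1), "fpr")
  )
  usable <- !is.na(summary_df$fpr)
  if (!any(usable)) stop("no grid point retains any PSM", call. = FALSE)
  feasible <- usable & summary_df$fpr <= fpr_max
  pick_from <- if (any(feasible)) which(feasible) else which(usable)
  if (any(feasible)) {
    # max peptides, then min FPR, then highest threshold
    ord <- order(-summary_df$n_peptides_fwd[pick_from],
                 summary_df$fpr[pick_from],
                 -summary_df$min_ion_score[pick_from])
  } else {
    ord <- order(summary_df$fpr[pick_from],
                 -summary_df$min_ion_score[pick_from])
  }
  best <- pick_from[ord[1L]]
  out <- res[[best]]
  out$constraint_met <- any(feasible)
  out$grid <- grid
  out$grid_summary <- summary_df
  if (!out$constraint_met)
    warning(sprintf("no score threshold on the grid achieves FPR <= %g; returning the minimal-FPR point (FPR = %.4g)",
                    fpr_max, out$fpr))
  out
}
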