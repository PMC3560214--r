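# Gel-band molecular-weight concordance: compare each protein's theoretical
# (sequence-derived) MW with the observed MW range of the SDS-PAGE band it
# was identified in. A theoretical MW above the band's upper bound means the
# observed fragment ran lighter than the intact protein -> likely
# degraded/truncated; below the lower bound -> ran heavier than expected ->
# potentially post-translationally modified.

#' Classify a protein against a gel band's observed MW range
#'
#' @param theoretical_mw_kda Theoretical molecular weight(s), kDa; must be
#'   positive.
#' @param mw_lower_kda,mw_upper_kda Observed MW bounds of the band (kDa).
#' @return Character vector with values `"degraded"` (MW strictly above the
#'   upper bound), `"modified"` (strictly below the lower bound) or
#'   `"concordant"` (within bounds, inclusive).
#' @export
classify_protein <- function(theoretical_mw_kda, mw_lower_kda, mw_upper_kda) {
  if (any(!is.finite(theoretical_mw_kda)) || any(theoretical_mw_kda <= 0))
    stop("theoretical MW must be positive and finite", call. = FALSE)
  if (mw_upper_kda <= mw_lower_kda || mw_lower_kda <= 0)
    stop("band bounds must satisfy 0 < lower < upper", call. = FALSE)
  ifelse(theoretical_mw_kda > mw_upper_kda, "degraded",
         ifelse(theoretical_mw_kda < mw_lower_kda, "modified", "concordant"))
}

#' Construct a gel band
#'
#' @param index Band index (1 = top of the gel, highest MW).
#' @param mw_lower_kda,mw_upper_kda Observed MW bounds from the marker lane.
#' @param members Data frame with columns `accession`, `theoretical_mw_kda`,
#'   `ms_signal` for proteins identified in this band.
#' @return Object of class `gel_band`.
#' @export
gel_band <- function(index, mw_lower_kda, mw_upper_kda,
                     members = data.frame(accession = character(0),
                                          theoretical_mw_kda = numeric(0),
                                          ms_signal = numeric(0))) {
  stopifnot(is.data.frame(members),
            all(c("accession", "theoretical_mw_kda", "ms_signal") %in% names(members)))
  if (mw_upper_kda <= mw_lower_kda || mw_lower_kda <= 0)
    stop("band bounds must satisfy 0 < lower < upper", call. = FALSE)
  structure(list(index = as.integer(index), mw_lower_kda = mw_lower_kda,
                 mw_upper_kda = mw_upper_kda, members = members),
            class = "gel_band")
}

#' Summarize one gel band
#'
#' Computes the member count, mean and sample SD (n - 1) of theoretical MWs,
#' and the signal-weighted percentages of degraded, modified and concordant
#' members: `pct_signal_degraded = 100 * (signal of members with MW above
#' the band) / (total member signal)`, and analogously for the others. The
#' three percentages sum to 100 exactly.
#'
#' @param band A [gel_band()].
#' @return One-row data frame (class `band_report`) with columns `index`,
#'   `n_proteins`, `mean_theoretical_mw_kda`, `sd_theoretical_mw_kda`,
#'   `pct_signal_degraded`, `pct_signal_modified`, `pct_signal_concordant`.
#'   An empty band yields `n_proteins = 0` and `NA` statistics.
#' @export
band_summary <- function(band) {
  stopifnot(inherits(band, "gel_band"))
  m <- band$members
  if (nrow(m) == 0L) {
    out <- data.frame(index = band$index, n_proteins = 0L,
                      mean_theoretical_mw_kda = NA_real_,
                      sd_theoretical_mw_kda = NA_real_,
                      pct_signal_degraded = NA_real_,
                      pct_signal_modified = NA_real_,
                      pct_signal_concordant = NA_real_)
    class(out) <- c("band_report", "data.frame")
    return(out)
  }
  cls <- classify_protein(m$theoretical_mw_kda, band$mw_lower_kda, band$mw_upper_kda)
  total <- sum(m$ms_signal)
  pct <- function(which) {
    if (total <= 0) return(NA_real_)
    100 * sum(m$ms_signal[cls == which]) / total
  }
  out <- data.frame(
    index = band$index,
    n_proteins = nrow(m),
    mean_theoretical_mw_kda = mean(m$theoretical_mw_kda),
    sd_theoretical_mw_kda = if (nrow(m) > 1L) stats::sd(m$theoretical_mw_kda) else NA_real_,
    pct_signal_degraded = pct("degraded"),
    pct_signal_modified = pct("modified"),
    pct_signal_concordant = pct("concordant"))
  class(out) <- c("band_report", "data.frame")
  out
}

#' Gel-band report for a whole lane
#'
#' Builds one [gel_band()] per row of `bounds` from the band-assignment
#' table, summarizes each, and appends the signal-weighted overall degraded
#' percentage across bands (total degraded signal over total signal, which
#' is how the per-band values aggregate to a lane-level figure). Proteins
#' with `NA` theoretical MW (e.g. sequences containing `X`) are dropped with
#' a warning.
#'
#' @param assignments Data frame with columns `accession`, `band_index`,
#'   `ms_signal` (a protein found in two bands appears once per band).
#' @param bounds Data frame with columns `band_index`, `mw_lower_kda`,
#'   `mw_upper_kda`.
#' @param mw_table Data frame with columns `accession`,
#'   `theoretical_mw_kda` (see [theoretical_mw_table()]).
#' @return List with `bands` (row-bound `band_report`s) and
#'   `overall_pct_degraded`.
#' @export
gel_lane_report <- function(assignments, bounds, mw_table) {
  stopifnot(all(c("accession", "band_index", "ms_signal") %in% names(assignments)),
            all(c("band_index", "mw_lower_kda", "mw_upper_kda") %in% names(bounds)))
  mw <- stats::setNames(mw_table$theoretical_mw_kda, mw_table$accession)
  unknown <- setdiff(assignments$accession, names(mw))
  if (length(unknown) > 0L)
    stop(sprintf("no theoretical MW for: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  asg <- assignments
  asg$theoretical_mw_kda <- unname(mw[asg$accession])
  if (anyNA(asg$theoretical_mw_kda)) {
    warning(sprintf("dropping %d assignment(s) with undefined theoretical MW",
                    sum(is.na(asg$theoretical_mw_kda))))
    asg <- asg[!is.na(asg$theoretical_mw_kda), , drop = FALSE]
  }
  bounds <- bounds[order(-bounds$mw_upper_kda), , drop = FALSE]
  reports <- list()
  degraded_signal <- 0
  total_signal <- 0
  for (i in seq_len(nrow(bounds))) {
    b <- bounds[i, ]
    mem <- asg[asg$band_index == b$band_index,
               c("accession", "theoretical_mw_kda", "ms_signal")]
    band <- gel_band(b$band_index, b$mw_lower_kda, b$mw_upper_kda, mem)
    rep_i <- band_summary(band)
    reports[[i]] <- rep_i
    if (nrow(mem) > 0L) {
      cls <- classify_protein(mem$theoretical_mw_kda, b$mw_lower_kda, b$mw_upper_kda)
      degraded_signal <- degraded_signal + sum(mem$ms_signal[cls == "degraded"])
      total_signal <- total_signal + sum(mem$ms_signal)
    }
  }
  bands <- do.call(rbind, reports)
  list(bands = bands,
       overall_pct_degraded = if (total_signal > 0) 100 * degraded_signal / total_signal
                              else NA_real_)
}

#' Infer band MW bounds from the marker lane
#'
#' SDS-PAGE migration is modelled as linear in log10(MW): marker positions
#' define the calibration, band edge positions are interpolated, and
#' consecutive edges become each band's (upper, lower) observed MW bounds.
#' Edges beyond the outermost markers are clamped to the nearest marker MW
#' and flagged.
#'
#' @param marker_lane Data frame with columns `position` (migration
#'   distance, increasing down the gel) and `mw_kda` (known marker MW);
#'   at least two markers, positions strictly monotone with MW decreasing
#'   as position increases.
#' @param band_edges Numeric vector of n_bands + 1 edge positions,
#'   increasing.
#' @return Data frame with columns `band_index`, `mw_lower_kda`,
#'   `mw_upper_kda`, `extrapolated` (TRUE when either edge was clamped).
#' @export
infer_band_bounds <- function(marker_lane, band_edges) {
  stopifnot(all(c("position", "mw_kda") %in% names(marker_lane)))
  if (nrow(marker_lane) < 2L) stop("need at least 2 markers", call. = FALSE)
  pos <- marker_lane$position
  if (any(diff(pos) <= 0)) stop("marker positions must be strictly increasing", call. = FALSE)
  if (any(diff(marker_lane$mw_kda) >= 0))
    stop("marker MW must decrease with migration position", call. = FALSE)
  if (length(band_edges) < 2L || any(diff(band_edges) <= 0))
    stop("band edges must be at least 2 strictly increasing positions", call. = FALSE)
  fit <- stats::approx(pos, log10(marker_lane$mw_kda), xout = band_edges, rule = 2)
  mw_at_edge <- 10^fit$y
  clamped <- band_edges < min(pos) | band_edges > max(pos)
  n <- length(band_edges) - 1L
  data.frame(band_index = seq_len(n),
             mw_lower_kda = mw_at_edge[-1L],
             mw_upper_kda = mw_at_edge[-(n + 1L)],
             extrapolated = clamped[-(n + 1L)] | clamped[-1L])
}
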