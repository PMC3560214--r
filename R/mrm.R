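# Targeted (SRM/MRM) quantification: sum trace intensities within a mass
# tolerance of each signature fragment ion, call peptide presence from the
# number of matched fragments, and express sample levels relative to the
# median of untreated controls.

#' Construct a transition set
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param peptide Signature peptide sequence.
#' @param fragment_mzs Fragment ion m/z values (Th); stored sorted and
#'   unique.
#' @param tolerance_da Half-width of the fragment matching window (Da).
#' @return Object of class `transition_set`.
#' @export
transition_set <- function(precursor_mz, peptide, fragment_mzs,
                           tolerance_da = 0.05) {
  if (length(fragment_mzs) == 0L) stop("empty fragment list", call. = FALSE)
  if (any(fragment_mzs <= 0) || precursor_mz <= 0)
    stop("m/z values must be positive", call. = FALSE)
  if (tolerance_da <= 0) stop("tolerance_da must be > 0", call. = FALSE)
  structure(list(precursor_mz = precursor_mz, peptide = peptide,
                 fragment_mzs = sort(unique(fragment_mzs)),
                 tolerance_da = tolerance_da),
            class = "transition_set")
}

#' Transition set for the BBB-crossing single-domain antibody FC5
#'
#' The signature tryptic peptide ITWGGDNTFYSNSVK (doubly charged precursor
#' at m/z 844.92) with its four signature fragment ions.
#'
#' @param tolerance_da Fragment matching half-window (Da).
#' @return A [transition_set()].
#' @export
fc5_transitions <- function(tolerance_da = 0.05) {
  transition_set(precursor_mz = 844.92,
                 peptide = "ITWGGDNTFYSNSVK",
                 fragment_mzs = c(534.48, 729.47, 737.89, 1288.44),
                 tolerance_da = tolerance_da)
}

#' Extract transition signals from an MRM trace
#'
#' For each fragment m/z in the transition set, sums the intensities of
#' every trace point within `tolerance_da` of it (inclusive window); the
#' per-trace total is the sum over fragments. The result is invariant to
#' trace point order and additive over partitions of the trace.
#'
#' @param trace Data frame with columns `mz`, `intensity` (see
#'   [read_trace_table()]).
#' @param transitions A [transition_set()].
#' @return List with `signals` (data frame `fragment_mz`,
#'   `matched_intensity`, `n_trace_points_matched`) and `total`.
#' @export
extract_transition_signal <- function(trace, transitions) {
  stopifnot(inherits(transitions, "transition_set"))
  stopifnot(all(c("mz", "intensity") %in% names(trace)))
  tol <- transitions$tolerance_da
  signals <- do.call(rbind, lapply(transitions$fragment_mzs, function(f) {
    hit <- abs(trace$mz - f) <= tol
    data.frame(fragment_mz = f,
               matched_intensity = sum(trace$intensity[hit]),
               n_trace_points_matched = sum(hit))
  }))
  if (is.null(signals)) signals <- data.frame(fragment_mz = numeric(0),
                                              matched_intensity = numeric(0),
                                              n_trace_points_matched = integer(0))
  list(signals = signals, total = sum(signals$matched_intensity))
}

#' Call peptide presence from matched transitions
#'
#' @param signals The `signals` data frame from
#'   [extract_transition_signal()].
#' @param min_fragments_matched Minimum number of fragments with non-zero
#'   matched intensity required for a positive call (at least 1).
#' @return `TRUE` if the peptide is called present.
#' @export
detect_peptide <- function(signals, min_fragments_matched = 2L) {
  if (min_fragments_matched < 1L)
    stop("min_fragments_matched must be >= 1", call. = FALSE)
  sum(signals$matched_intensity > 0) >= min_fragments_matched
}

# Lower median: for even counts, the lower of the two middle order
# statistics, so the normalization anchor is an actually observed value.
.median_lower <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Levels relative to the median untreated control
#'
#' Each sample's relative level is its raw signal divided by the median of
#' the control samples' raw signals (lower-median convention for even
#' control counts), so the control median normalizes to exactly 1.
#'
#' @param samples Named numeric vector of raw transition signals, one per
#'   sample.
#' @param control_ids Names of the control ("untreated") samples; at least
#'   one with positive signal.
#' @return Data frame with columns `sample_id`, `raw_signal`,
#'   `relative_to_median_control`, `is_control`.
#' @export
relative_level <- function(samples, control_ids) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named vector", call. = FALSE)
  missing <- setdiff(control_ids, names(samples))
  if (length(missing) > 0L)
    stop(sprintf("control id(s) not in samples: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (length(control_ids) == 0L) stop("at least one control is required", call. = FALSE)
  anchor <- .median_lower(samples[control_ids])
  if (!is.finite(anchor) || anchor <= 0)
    stop("control median signal must be positive", call. = FALSE)
  data.frame(sample_id = names(samples),
             raw_signal = unname(samples),
             relative_to_median_control = unname(samples) / anchor,
             is_control = names(samples) %in% control_ids,
             stringsAsFactors = FALSE)
}
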