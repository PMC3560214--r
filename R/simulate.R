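# Synthetic-data generator: every fixture the pipeline consumes, with
# planted ground truth (decoy score gap, marker signal enrichment, per-band
# degraded signal, bipartite surface edge density, spiked MRM transitions),
# fully reproducible from a seed.

AA20 <- names(AA_AVERAGE_RESIDUE_MASS_DA)
PROTON_MASS_DA <- 1.00728

.with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Location-shifted Gumbel deviates parameterized by mean and sd: the heavy
# right tail mimics search-engine ion-score behaviour.
.rgumbel <- function(n, mean, sd) {
  scale <- sd * sqrt(6) / pi
  loc <- mean - 0.5772156649 * scale
  loc - scale * log(-log(stats::runif(n)))
}

# Random tryptic-like peptides: canonical letters, C-terminal K or R.
.random_peptides <- function(n, min_len = 7L, max_len = 20L) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  body <- vapply(len, function(l) {
    paste(sample(AA20, l - 1L, replace = TRUE), collapse = "")
  }, character(1))
  paste0(body, sample(c("K", "R"), n, replace = TRUE))
}

.check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("invalid config field '%s'", name), call. = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic EMV proteomics experiment. Defaults encode
#' the study conditions the pipeline is designed around: a 1179-protein
#' identification list, a 3.3-fold marker-family signal enrichment, about
#' 20% of gel-band signal from degraded proteins, a 35% cell-surface
#' fraction, and an equal-size forward+reverse composite search (decoy
#' fraction 0.5).
#'
#' @param seed Integer RNG seed; identical config implies byte-identical
#'   generated fixtures.
#' @param n_forward_psms Number of forward-database PSMs.
#' @param decoy_fraction Decoy share of the composite PSM table, in (0, 1);
#'   the decoy count is `round(n_forward_psms * decoy_fraction /
#'   (1 - decoy_fraction))`.
#' @param forward_score_mean,forward_score_sd Moments of the forward ion
#'   score distribution (location-shifted Gumbel).
#' @param decoy_score_mean,decoy_score_sd Moments of the (lower-scoring)
#'   decoy ion score distribution.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param marker_fraction Fraction of proteins belonging to marker
#'   families, in (0, 1).
#' @param marker_enrichment Planted fold-increase of per-protein MS signal
#'   for marker-family proteins (> 0).
#' @param degraded_fraction Planted fraction of each gel band's signal
#'   contributed by proteins heavier than the band's upper bound, in
#'   \[0, 1). The top band has no heavier donors and stays at 0.
#' @param surface_fraction Fraction of proteins annotated as cell-surface,
#'   in (0, 1).
#' @param edge_density Probability of a PPI edge between any (EMV surface,
#'   target surface) protein pair, in \[0, 1\].
#' @param n_bands Number of gel bands (default 10).
#' @param prob_range Optional length-2 numeric: when set, PSM probabilities
#'   are drawn uniformly on this interval instead of being score-linked.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_forward_psms = 1000L,
                       decoy_fraction = 0.5,
                       forward_score_mean = 55, forward_score_sd = 12,
                       decoy_score_mean = 12, decoy_score_sd = 5,
                       n_proteins = 1179L,
                       marker_fraction = 0.1,
                       marker_enrichment = 3.3,
                       degraded_fraction = 0.2,
                       surface_fraction = 0.35,
                       edge_density = 0.01,
                       n_bands = 10L,
                       prob_range = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("invalid config field 'seed'", call. = FALSE)
  if (!is.numeric(n_forward_psms) || n_forward_psms < 1 ||
      n_forward_psms != round(n_forward_psms))
    stop("invalid config field 'n_forward_psms'", call. = FALSE)
  .check_fraction(decoy_fraction, "decoy_fraction")
  if (!is.numeric(n_proteins) || n_proteins < 1 || n_proteins != round(n_proteins))
    stop("invalid config field 'n_proteins'", call. = FALSE)
  .check_fraction(marker_fraction, "marker_fraction")
  if (!is.numeric(marker_enrichment) || marker_enrichment <= 0)
    stop("invalid config field 'marker_enrichment'", call. = FALSE)
  .check_fraction(degraded_fraction, "degraded_fraction", open_lo = FALSE)
  .check_fraction(surface_fraction, "surface_fraction")
  .check_fraction(edge_density, "edge_density", open_lo = FALSE, open_hi = FALSE)
  if (!is.numeric(n_bands) || n_bands < 2 || n_bands != round(n_bands))
    stop("invalid config field 'n_bands'", call. = FALSE)
  if (!is.null(prob_range)) {
    if (!is.numeric(prob_range) || length(prob_range) != 2L ||
        prob_range[1] < 0 || prob_range[2] > 1 || prob_range[1] >= prob_range[2])
      stop("invalid config field 'prob_range'", call. = FALSE)
  }
  if (decoy_score_mean >= forward_score_mean)
    stop("invalid config field 'decoy_score_mean' (must be below forward_score_mean)",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_forward_psms = as.integer(n_forward_psms),
                 decoy_fraction = decoy_fraction,
                 forward_score_mean = forward_score_mean,
                 forward_score_sd = forward_score_sd,
                 decoy_score_mean = decoy_score_mean,
                 decoy_score_sd = decoy_score_sd,
                 n_proteins = as.integer(n_proteins),
                 marker_fraction = marker_fraction,
                 marker_enrichment = marker_enrichment,
                 degraded_fraction = degraded_fraction,
                 surface_fraction = surface_fraction,
                 edge_density = edge_density,
                 n_bands = as.integer(n_bands),
                 prob_range = prob_range),
            class = "sim_config")
}

#' Generate a synthetic forward+decoy PSM table
#'
#' Forward and decoy ion scores come from two location-shifted Gumbel
#' distributions (decoy mean below forward mean). Probabilities are
#' score-linked through a noisy logistic link, except that a small, fixed
#' fraction (2%) of decoys receives a spuriously high probability --
#' without it the probability gate alone would remove essentially every
#' decoy and the score-threshold search would be unconstrained. Mass-error
#' and missed-cleavage fields are drawn so that a known subset of rows
#' violates each filter gate.
#'
#' @param config A [sim_config()].
#' @return PSM data frame in the shape of [read_psm_table()] output
#'   (including the derived `is_decoy` column): exactly
#'   `n_forward_psms` forward rows followed by the implied number of decoy
#'   rows.
#' @export
generate_psm_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n_fwd <- config$n_forward_psms
    n_dec <- round(n_fwd * config$decoy_fraction / (1 - config$decoy_fraction))
    n <- n_fwd + n_dec
    is_decoy <- rep(c(FALSE, TRUE), c(n_fwd, n_dec))
    score <- numeric(n)
    score[!is_decoy] <- .rgumbel(n_fwd, config$forward_score_mean, config$forward_score_sd)
    score[is_decoy] <- .rgumbel(n_dec, config$decoy_score_mean, config$decoy_score_sd)
    score <- pmax(0, score)
    if (is.null(config$prob_range)) {
      prob <- stats::plogis((score - 35 + stats::rnorm(n, 0, 3)) / 6)
      lucky <- is_decoy & stats::runif(n) < 0.02
      prob[lucky] <- stats::runif(sum(lucky), 0.85, 1)
    } else {
      prob <- stats::runif(n, config$prob_range[1], config$prob_range[2])
    }
    parent <- stats::rnorm(n, 0, 0.04)
    wild <- stats::runif(n) < 0.05
    parent[wild] <- sample(c(-1, 1), sum(wild), replace = TRUE) *
      stats::runif(sum(wild), 0.12, 0.35)
    fragment <- abs(stats::rnorm(n, 0, 0.07))
    wild <- stats::runif(n) < 0.05
    fragment[wild] <- stats::runif(sum(wild), 0.22, 0.5)
    accession <- sprintf("P%04d", sample.int(config$n_proteins, n, replace = TRUE))
    accession[is_decoy] <- paste0(DECOY_PREFIX, accession[is_decoy])
    df <- data.frame(
      spectrum_id = sprintf("S%06d", seq_len(n)),
      peptide = .random_peptides(n),
      proteins = accession,
      ion_score = round(score, 4),
      parent_error_da = round(parent, 5),
      fragment_error_da = round(fragment, 5),
      missed_cleavages = sample(0:2, n, replace = TRUE, prob = c(0.75, 0.20, 0.05)),
      charge = sample(2:4, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      probability = round(pmin(1, pmax(0, prob)), 5),
      stringsAsFactors = FALSE)
    df$is_decoy <- is_decoy
    df
  })
}

GO_CATEGORIES <- c("membrane_traffic", "rna_dna_binding", "cytoskeletal",
                   "enzyme", "receptor", "adhesion", "chaperone", "signaling")

#' Generate a complete synthetic EMV experiment
#'
#' Builds every fixture downstream stages consume -- synthetic proteome
#' (FASTA-ready sequences, families, surface flags, category annotations),
#' MS1 ion table with peptide-to-protein mapping, gel-band assignments and
#' marker-lane calibration, marker catalog, surface lists with a bipartite
#' PPI edge list, and MRM traces -- with all ground-truth quantities
#' planted at the values in `config` and recorded under `$planted`.
#'
#' Planted structure, by stage:
#' * marker-family proteins carry `marker_enrichment`-fold mean ion
#'   intensity;
#' * in every gel band below the top one, a `degraded_fraction` share of
#'   the band's signal is assigned to proteins heavier than the band's
#'   upper bound (the top band has no heavier donors, so its planted
#'   degraded share is 0);
#' * each (EMV surface, target surface) protein pair carries a PPI edge
#'   with probability `edge_density`, plus decoy edges touching
#'   intracellular proteins that no interaction count should include;
#' * one MRM trace per sample is spiked with the FC5 signature fragments
#'   (treated samples at 4-fold the untreated level), plus one strongly
#'   spiked reference trace and one blank.
#'
#' @param config A [sim_config()].
#' @return Object of class `emv_experiment`: a list of data frames and
#'   vectors (see Details), plus `planted` (ground truth) and `config`.
#' @export
generate_emv_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    n <- config$n_proteins

    ## proteome with family structure
    fam_sizes <- integer(0)
    while (sum(fam_sizes) < n) fam_sizes <- c(fam_sizes, sample(1:6, 1))
    fam_sizes[length(fam_sizes)] <- fam_sizes[length(fam_sizes)] - (sum(fam_sizes) - n)
    fam_sizes <- fam_sizes[fam_sizes > 0]
    family <- rep(sprintf("FAM%04d", seq_along(fam_sizes)), fam_sizes)
    accession <- sprintf("P%04d", seq_len(n))
    member_idx <- unlist(lapply(fam_sizes, seq_len))
    gene_symbol <- paste0(family, member_idx)

    target_mw <- 10^stats::runif(n, log10(11), log10(250))  # kDa
    len <- pmax(50L, as.integer(round(target_mw * 1000 / 110.6)))
    sequence <- vapply(len, function(l) {
      paste(sample(AA20, l, replace = TRUE), collapse = "")
    }, character(1))
    mw <- compute_theoretical_mw(sequence)
    is_surface <- stats::runif(n) < config$surface_fraction

    ## marker families: accumulate shuffled families until the marker
    ## protein share reaches marker_fraction
    fam_order <- sample(unique(family))
    fam_count <- table(family)[fam_order]
    n_marker_target <- round(config$marker_fraction * n)
    cum <- cumsum(fam_count)
    marker_families <- fam_order[seq_len(max(1L, which(cum >= n_marker_target)[1]))]
    is_marker <- family %in% marker_families

    proteins <- data.frame(accession = accession, gene_symbol = gene_symbol,
                           family_symbol = family, sequence = sequence,
                           theoretical_mw_kda = mw, is_surface = is_surface,
                           is_marker = is_marker, stringsAsFactors = FALSE)

    ## category annotations: one baseline category per protein, plus a
    ## planted membrane_traffic enrichment among marker proteins
    base_cat <- sample(GO_CATEGORIES, n, replace = TRUE)
    extra <- is_marker & stats::runif(n) < 0.8 & base_cat != "membrane_traffic"
    annotations <- rbind(
      data.frame(accession = accession, category = base_cat, stringsAsFactors = FALSE),
      data.frame(accession = accession[extra], category = "membrane_traffic",
                 stringsAsFactors = FALSE))
    annotations <- annotations[order(annotations$accession, annotations$category), ]
    rownames(annotations) <- NULL

    ## MS1 ions: a few peptides per protein, log-normal intensities,
    ## marker proteins enriched by the planted fold factor
    n_pep <- 1L + stats::rpois(n, 2)
    pep_owner <- rep(seq_len(n), n_pep)
    peptide <- .random_peptides(length(pep_owner), 8L, 16L)
    while (anyDuplicated(peptide)) {
      dup <- duplicated(peptide)
      peptide[dup] <- .random_peptides(sum(dup), 8L, 16L)
    }
    peptide_map <- data.frame(peptide = peptide, accession = accession[pep_owner],
                              stringsAsFactors = FALSE)
    charge <- sample(2:3, length(peptide), replace = TRUE)
    pep_mass <- compute_theoretical_mw(peptide) * 1000
    intensity <- stats::rlnorm(length(peptide), meanlog = log(1e6), sdlog = 1)
    intensity[is_marker[pep_owner]] <- intensity[is_marker[pep_owner]] * config$marker_enrichment
    ions <- data.frame(mz = round((pep_mass + charge * PROTON_MASS_DA) / charge, 4),
                       charge = charge,
                       rt_min = round(stats::runif(length(peptide), 10, 70), 3),
                       intensity = round(intensity, 3),
                       peptide = peptide, stringsAsFactors = FALSE)
    n_noise <- round(0.1 * nrow(ions))
    if (n_noise > 0) {
      ions <- rbind(ions, data.frame(
        mz = round(stats::runif(n_noise, 400, 2000), 4),
        charge = sample(1:3, n_noise, replace = TRUE),
        rt_min = round(stats::runif(n_noise, 10, 70), 3),
        intensity = round(stats::rlnorm(n_noise, log(3e5), 1), 3),
        peptide = "", stringsAsFactors = FALSE))
    }
    rownames(ions) <- NULL
    protein_signal <- tapply(ions$intensity[nzchar(ions$peptide)],
                             peptide_map$accession[match(ions$peptide[nzchar(ions$peptide)],
                                                         peptide_map$peptide)], sum)
    ms_signal <- as.numeric(protein_signal[accession])
    ms_signal[is.na(ms_signal)] <- 0

    ## gel bands: log-spaced bounds spanning the proteome MW range
    edges_mw <- 10^seq(log10(260), log10(10), length.out = config$n_bands + 1L)
    band_bounds <- data.frame(band_index = seq_len(config$n_bands),
                              mw_lower_kda = edges_mw[-1L],
                              mw_upper_kda = edges_mw[-(config$n_bands + 1L)])
    home_band <- findInterval(-mw, -edges_mw, rightmost.closed = TRUE)
    in_gel <- home_band >= 1L & home_band <= config$n_bands
    assignments <- data.frame(accession = accession[in_gel],
                              band_index = home_band[in_gel],
                              ms_signal = ms_signal[in_gel],
                              stringsAsFactors = FALSE)
    planted_degraded <- stats::setNames(numeric(config$n_bands),
                                        seq_len(config$n_bands))
    f <- config$degraded_fraction
    if (f > 0) {
      for (b in 2:config$n_bands) {
        in_band <- assignments$band_index == b
        s_b <- sum(assignments$ms_signal[in_band])
        donors <- which(mw > band_bounds$mw_upper_kda[b])
        if (s_b <= 0 || length(donors) == 0L) next
        k <- max(1L, round(0.15 * sum(in_band)))
        pick <- donors[sample.int(length(donors), min(k, length(donors)))]
        w <- stats::runif(length(pick)); w <- w / sum(w)
        assignments <- rbind(assignments, data.frame(
          accession = accession[pick], band_index = b,
          ms_signal = s_b * f / (1 - f) * w, stringsAsFactors = FALSE))
        planted_degraded[b] <- f
      }
      rownames(assignments) <- NULL
    }

    ## marker-lane calibration consistent with the log-linear model
    marker_mw <- c(250, 150, 100, 75, 50, 37, 25, 20, 15, 10)
    pos_of <- function(m) (log10(260) - log10(m)) / (log10(260) - log10(10))
    marker_lane <- data.frame(position = pos_of(marker_mw), mw_kda = marker_mw)
    band_edges <- pos_of(edges_mw)

    ## marker catalog: detected families plus a few absent ones
    n_absent <- max(1L, round(0.12 * length(marker_families)))
    marker_catalog <- data.frame(
      identifier = c(sort(marker_families), sprintf("ABSENT%02d", seq_len(n_absent))),
      stringsAsFactors = FALSE)

    ## surface lists + bipartite PPI edges at the planted density
    emv_surface <- accession[is_surface]
    n_target <- max(20L, round(0.25 * n))
    target_surface <- sprintf("A%04d", seq_len(n_target))
    pairs <- expand.grid(emv = emv_surface, target = target_surface,
                         stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < config$edge_density
    planted_edges <- pairs[keep, , drop = FALSE]
    intracellular <- accession[!is_surface]
    n_decoy_edges <- max(0L, round(0.1 * nrow(planted_edges)))
    decoy_edges <- if (n_decoy_edges > 0) data.frame(
      emv = sample(intracellular, n_decoy_edges, replace = TRUE),
      target = sample(target_surface, n_decoy_edges, replace = TRUE),
      stringsAsFactors = FALSE) else NULL
    all_edges <- rbind(planted_edges, decoy_edges)
    flip <- stats::runif(nrow(all_edges)) < 0.5  # exercise unordered matching
    ppi_edges <- data.frame(
      protein_a = ifelse(flip, all_edges$target, all_edges$emv),
      protein_b = ifelse(flip, all_edges$emv, all_edges$target),
      stringsAsFactors = FALSE)
    rownames(ppi_edges) <- NULL

    ## MRM traces: backgrounds kept clear of the signature fragments
    transitions <- fc5_transitions()
    background <- function(npts, scale) {
      mz <- stats::runif(npts, 400, 2000)
      for (it in 1:10) {
        near <- vapply(mz, function(m) any(abs(m - transitions$fragment_mzs) < 0.2),
                       logical(1))
        if (!any(near)) break
        mz[near] <- stats::runif(sum(near), 400, 2000)
      }
      data.frame(mz = round(mz, 4),
                 intensity = round(stats::rlnorm(npts, log(scale), 0.5), 3))
    }
    spike <- function(scale) {
      do.call(rbind, lapply(transitions$fragment_mzs, function(fmz) {
        npts <- sample(2:4, 1)
        data.frame(mz = round(fmz + stats::runif(npts, -0.03, 0.03), 4),
                   intensity = round(stats::rlnorm(npts, log(scale), 0.3), 3))
      }))
    }
    sample_ids <- c("untreated_1", "untreated_2", "untreated_3",
                    "treated_1", "treated_2", "treated_3")
    traces <- stats::setNames(lapply(sample_ids, function(id) {
      scale <- if (startsWith(id, "treated")) 4e4 else 1e4
      rbind(background(60, 2e3), spike(scale))
    }), sample_ids)
    traces$spiked <- rbind(background(60, 2e3), spike(1e5))
    traces$blank <- background(60, 2e3)
    traces <- lapply(traces, function(tr) { rownames(tr) <- NULL; tr })

    structure(list(
      proteins = proteins,
      ions = ions,
      peptide_map = peptide_map,
      band_assignments = assignments,
      band_bounds = band_bounds,
      marker_lane = marker_lane,
      band_edges = band_edges,
      marker_catalog = marker_catalog,
      annotations = annotations,
      emv_surface = emv_surface,
      target_surface = target_surface,
      ppi_edges = ppi_edges,
      traces = traces,
      control_ids = c("untreated_1", "untreated_2", "untreated_3"),
      transitions = transitions,
      planted = list(
        marker_enrichment = config$marker_enrichment,
        marker_accessions = accession[is_marker],
        marker_families = marker_families,
        degraded_by_band = planted_degraded,
        edge_density = config$edge_density,
        n_planted_edges = nrow(planted_edges),
        overrep_category = "membrane_traffic"),
      config = config
    ), class = "emv_experiment")
  })
}

#' Write a synthetic experiment bundle to a directory
#'
#' Serializes every component of an [generate_emv_experiment()] bundle into
#' the plain-text dialects the readers in this package consume, so a
#' pipeline run can start from files alone.
#'
#' @param bundle An `emv_experiment`.
#' @param dir Target directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_emv_experiment <- function(bundle, dir) {
  stopifnot(inherits(bundle, "emv_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  .write_tsv(bundle$proteins[c("accession", "gene_symbol", "family_symbol",
                               "theoretical_mw_kda", "is_surface")],
             file.path(dir, "proteins.tsv"))
  write_ion_table(bundle$ions, file.path(dir, "ions.tsv"))
  write_peptide_map(bundle$peptide_map, file.path(dir, "peptide_map.tsv"))
  .write_tsv(bundle$band_assignments, file.path(dir, "band_assignments.tsv"))
  .write_tsv(bundle$band_bounds, file.path(dir, "band_bounds.tsv"))
  .write_tsv(bundle$marker_lane, file.path(dir, "marker_lane.tsv"))
  write_catalog(bundle$marker_catalog, file.path(dir, "marker_catalog.tsv"))
  .write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_catalog(data.frame(identifier = bundle$emv_surface),
                file.path(dir, "emv_surface.tsv"))
  write_catalog(data.frame(identifier = bundle$target_surface),
                file.path(dir, "target_surface.tsv"))
  write_edge_list(bundle$ppi_edges, file.path(dir, "edges.tsv"))
  for (id in names(bundle$traces)) {
    write_trace_table(bundle$traces[[id]], file.path(dir, "traces", paste0(id, ".tsv")))
  }
  cfg <- unclass(bundle$config)
  cfg$control_ids <- bundle$control_ids
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
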