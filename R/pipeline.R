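# End-to-end orchestration: a single YAML config names the inputs (a
# directory in the layout written by write_emv_experiment plus a PSM
# table), selects stages, and one call runs them in dependency order and
# writes a consolidated JSON report with per-stage TSVs.

PIPELINE_STAGES <- c("filter", "quant", "gel_bands", "enrichment",
                     "interactome", "mrm")

#' Validate a pipeline configuration file
#'
#' Reads a YAML pipeline config and validates it in full, reporting *all*
#' problems at once rather than failing on the first. Recognized fields:
#' `input_dir` (bundle directory), `psm_table`, `output_dir`, `stages`
#' (subset of `r paste(PIPELINE_STAGES, collapse = ", ")`; default all),
#' `seed`, `b_permutations`, `fpr_max`, `score_grid`,
#' `min_fragments_matched`, `control_ids`.
#'
#' @param path Path to the YAML file.
#' @return Object of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  errors <- character(0)
  cfg <- list(
    input_dir = raw$input_dir,
    psm_table = raw$psm_table,
    output_dir = if (is.null(raw$output_dir)) "pipeline_out" else raw$output_dir,
    stages = if (is.null(raw$stages)) PIPELINE_STAGES else unlist(raw$stages),
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    b_permutations = if (is.null(raw$b_permutations)) 100L else raw$b_permutations,
    fpr_max = if (is.null(raw$fpr_max)) 0.005 else raw$fpr_max,
    score_grid = if (is.null(raw$score_grid)) seq(10, 80, by = 5) else unlist(raw$score_grid),
    min_fragments_matched = if (is.null(raw$min_fragments_matched)) 2L
                            else raw$min_fragments_matched,
    control_ids = unlist(raw$control_ids))
  bad_stage <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad_stage) > 0L)
    errors <- c(errors, sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  if ("filter" %in% cfg$stages && is.null(cfg$psm_table))
    errors <- c(errors, "field 'psm_table' is required when the filter stage is enabled")
  if (!is.null(cfg$psm_table) && !file.exists(cfg$psm_table))
    errors <- c(errors, sprintf("field 'psm_table': file not found: %s", cfg$psm_table))
  needs_bundle <- length(intersect(cfg$stages, setdiff(PIPELINE_STAGES, "filter"))) > 0L
  if (needs_bundle) {
    if (is.null(cfg$input_dir))
      errors <- c(errors, "field 'input_dir' is required for the enabled stages")
    else if (!dir.exists(cfg$input_dir))
      errors <- c(errors, sprintf("field 'input_dir': directory not found: %s", cfg$input_dir))
  }
  if (!is.numeric(cfg$fpr_max) || cfg$fpr_max <= 0 || cfg$fpr_max > 1)
    errors <- c(errors, "field 'fpr_max' must be in (0, 1]")
  if (!is.numeric(cfg$b_permutations) || cfg$b_permutations < 1)
    errors <- c(errors, "field 'b_permutations' must be a positive integer")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    errors <- c(errors, "field 'seed' must be an integer")
  if (!is.numeric(cfg$score_grid) || length(cfg$score_grid) == 0L)
    errors <- c(errors, "field 'score_grid' must be a non-empty numeric vector")
  if (length(errors) > 0L) {
    stop(paste0("invalid pipeline config:\n", paste0("  - ", errors, collapse = "\n")),
         call. = FALSE)
  }
  cfg$config_path <- path
  structure(cfg, class = "pipeline_config")
}

.trace_files <- function(dir) {
  files <- list.files(file.path(dir, "traces"), pattern = "\\.tsv$", full.names = TRUE)
  stats::setNames(files, sub("\\.tsv$", "", basename(files)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (filter, then the
#' independent downstream stages), writes a consolidated `report.json` and
#' per-stage TSVs under `output_dir`, and returns the report. A failing
#' stage is recorded under `$errors` and does not stop independent stages.
#' Given the same config (and thus seeds), the report body is
#' byte-identical across reruns.
#'
#' @param config A [validate_config()] result.
#' @return Object of class `pipeline_report` (invisibly also written as
#'   JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(provenance = list(
    package = "emvprofiler",
    version = as.character(utils::packageVersion("emvprofiler")),
    config_hash = unname(tools::md5sum(config$config_path)),
    seed = as.integer(config$seed),
    stages = config$stages))
  errors <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  dir <- config$input_dir

  report$filter <- run_stage("filter", function() {
    psms <- read_psm_table(config$psm_table)
    res <- optimize_thresholds(psms, fpr_max = config$fpr_max,
                               grid = config$score_grid)
    write_psm_table(res$retained, file.path(config$output_dir, "retained_psms.tsv"))
    list(min_ion_score = res$thresholds_used$min_ion_score,
         n_fwd = res$n_fwd, n_rev = res$n_rev, fpr = res$fpr,
         n_peptides_fwd = res$n_peptides_fwd,
         n_peptides_rev = res$n_peptides_rev,
         fpr_peptides = res$fpr_peptides,
         constraint_met = res$constraint_met)
  })

  needs_quant_inputs <- any(c("quant", "gel_bands", "enrichment") %in% config$stages)
  if (needs_quant_inputs || "interactome" %in% config$stages || "mrm" %in% config$stages) {
    proteins <- if (needs_quant_inputs)
      .read_tsv_raw(file.path(dir, "proteins.tsv")) else NULL
    if (!is.null(proteins))
      proteins$theoretical_mw_kda <- as.numeric(proteins$theoretical_mw_kda)
  }

  marker_members <- NULL
  if (any(c("quant", "enrichment") %in% config$stages)) {
    catalog <- read_catalog(file.path(dir, "marker_catalog.tsv"))
    marker_members <- proteins$accession[proteins$family_symbol %in% catalog$identifier]
  }

  report$quant <- run_stage("quant", function() {
    ions <- read_ion_table(file.path(dir, "ions.tsv"))
    pmap <- read_peptide_map(file.path(dir, "peptide_map.tsv"))
    sf <- signal_fraction(ions, pmap, marker_members, group_id = "marker_families")
    .write_tsv(sf, file.path(config$output_dir, "signal_report.tsv"))
    enr <- marker_enrichment_estimate(ions, pmap, marker_members, proteins$accession)
    list(marker_signal_fraction = sf$fraction,
         marker_signal = sf$group_signal, total_signal = sf$total_signal,
         marker_enrichment_fold = enr)
  })

  report$gel_bands <- run_stage("gel_bands", function() {
    assignments <- .read_tsv_raw(file.path(dir, "band_assignments.tsv"))
    assignments$band_index <- as.integer(assignments$band_index)
    assignments$ms_signal <- as.numeric(assignments$ms_signal)
    bounds <- .read_tsv_raw(file.path(dir, "band_bounds.tsv"))
    for (col in c("mw_lower_kda", "mw_upper_kda")) bounds[[col]] <- as.numeric(bounds[[col]])
    bounds$band_index <- as.integer(bounds$band_index)
    lane <- gel_lane_report(assignments, bounds,
                            proteins[c("accession", "theoretical_mw_kda")])
    .write_tsv(lane$bands, file.path(config$output_dir, "band_report.tsv"))
    list(bands = lane$bands, overall_pct_degraded = lane$overall_pct_degraded)
  })

  report$enrichment <- run_stage("enrichment", function() {
    catalog <- read_catalog(file.path(dir, "marker_catalog.tsv"))
    annotations <- .read_tsv_raw(file.path(dir, "annotations.tsv"))
    identified <- proteins$accession
    vn <- venn(list(identified = identified, marker_members = marker_members))
    ov <- marker_overlap(identified, catalog$identifier,
                         proteins[c("accession", "family_symbol")])
    cats <- sort(unique(annotations$category))
    over <- lapply(seq_along(cats), function(i) {
      r <- overrep_test(marker_members, identified, annotations, cats[i],
                        B = config$b_permutations, seed = config$seed + i)
      data.frame(category = r$category, observed = r$observed,
                 null_mean = mean(r$null_counts), p_empirical = r$p_empirical,
                 B = r$B)
    })
    over <- do.call(rbind, over)
    .write_tsv(over, file.path(config$output_dir, "overrepresentation.tsv"))
    list(venn = as.list(unclass(vn)),
         markers_found = ov$n_found, markers_total = ov$n_total,
         overrepresentation = over)
  })

  report$interactome <- run_stage("interactome", function() {
    emv <- read_catalog(file.path(dir, "emv_surface.tsv"))$identifier
    target <- read_catalog(file.path(dir, "target_surface.tsv"))$identifier
    edges <- read_edge_list(file.path(dir, "edges.tsv"))
    s <- count_interactions(emv, target, edges)
    write_edge_list(
      stats::setNames(s$edges, c("protein_a", "protein_b")),
      file.path(config$output_dir, "interactions.tsv"))
    list(n_emv_partnered = s$n_emv_partnered,
         n_target_partnered = s$n_target_partnered,
         n_interactions = s$n_interactions)
  })

  report$mrm <- run_stage("mrm", function() {
    transitions <- fc5_transitions()
    files <- .trace_files(dir)
    if (length(files) == 0L) stop("no trace files under input_dir/traces", call. = FALSE)
    extracted <- lapply(files, function(f) {
      extract_transition_signal(read_trace_table(f), transitions)
    })
    totals <- vapply(extracted, `[[`, numeric(1), "total")
    detected <- vapply(extracted, function(e)
      detect_peptide(e$signals, config$min_fragments_matched), logical(1))
    controls <- config$control_ids
    if (is.null(controls))
      controls <- grep("^untreated", names(totals), value = TRUE)
    quant_ids <- setdiff(names(totals), c("spiked", "blank"))
    levels <- relative_level(totals[quant_ids], intersect(controls, quant_ids))
    .write_tsv(levels, file.path(config$output_dir, "relative_levels.tsv"))
    list(detected = as.list(detected), levels = levels)
  })

  report$errors <- errors
  class(report) <- "pipeline_report"
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  writeLines(json, file.path(config$output_dir, "report.json"))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("EMV pipeline report (seed ", x$provenance$seed, ")\n", sep = "")
  for (stage in PIPELINE_STAGES) {
    if (is.null(x[[stage]])) next
    cat(" -", stage, "\n")
  }
  if (length(x$errors) > 0L) {
    cat(" failed stages:\n")
    for (nm in names(x$errors)) cat(sprintf("   %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}
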