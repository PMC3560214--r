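# In-silico cell-cell interactomics: count which surface proteins of the
# vesicles could engage surface proteins of a target cell type, given a
# reference protein-protein interaction edge list.

#' Count potential surface protein-protein interactions
#'
#' An interaction is any unordered PPI edge with one endpoint in the EMV
#' surface set and the other in the target-cell surface set (both
#' orientations of each edge are checked). A pair supported by several
#' database records counts once; a self-edge on a protein present in both
#' sets counts as one interaction with one partnered protein on each side.
#'
#' @param emv_surface Character vector of EMV surface accessions.
#' @param target_surface Character vector of target-cell surface accessions.
#' @param edges Data frame with columns `protein_a`, `protein_b`
#'   (undirected edges; see [read_edge_list()]).
#' @return Object of class `interaction_summary`: `n_emv_partnered`,
#'   `n_target_partnered`, `n_interactions`, and the `edges` data frame
#'   (`emv_accession`, `target_accession`) of distinct interacting pairs.
#' @export
count_interactions <- function(emv_surface, target_surface, edges) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(edges)))
  emv_surface <- unique(emv_surface)
  target_surface <- unique(target_surface)
  emv_side <- character(0)
  target_side <- character(0)
  pair_keys <- character(0)
  pair_emv <- character(0)
  pair_target <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    hit <- FALSE
    if (a %in% emv_surface && b %in% target_surface) {
      emv_side <- c(emv_side, a); target_side <- c(target_side, b); hit <- TRUE
    }
    if (b %in% emv_surface && a %in% target_surface) {
      emv_side <- c(emv_side, b); target_side <- c(target_side, a); hit <- TRUE
    }
    if (hit) {
      key <- paste(sort(c(a, b)), collapse = "\r")
      if (!key %in% pair_keys) {
        pair_keys <- c(pair_keys, key)
        if (a %in% emv_surface && b %in% target_surface) {
          pair_emv <- c(pair_emv, a); pair_target <- c(pair_target, b)
        } else {
          pair_emv <- c(pair_emv, b); pair_target <- c(pair_target, a)
        }
      }
    }
  }
  structure(list(
    n_emv_partnered = length(unique(emv_side)),
    n_target_partnered = length(unique(target_side)),
    n_interactions = length(pair_keys),
    edges = data.frame(emv_accession = pair_emv, target_accession = pair_target,
                       stringsAsFactors = FALSE)
  ), class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("%d EMV surface protein(s) could interact with %d target surface protein(s), forming %d theoretical protein-protein interaction(s)\n",
              x$n_emv_partnered, x$n_target_partnered, x$n_interactions))
  invisible(x)
}

#' Select surface-annotated proteins
#'
#' Surface localization is an input annotation (e.g. from GO cellular
#' component), never inferred from sequence; every protein must carry the
#' flag.
#'
#' @param proteins Data frame with columns `accession` and `is_surface`
#'   (logical).
#' @return Character vector of surface accessions.
#' @export
surface_filter <- function(proteins) {
  stopifnot(all(c("accession", "is_surface") %in% names(proteins)))
  flag <- proteins$is_surface
  if (is.character(flag)) flag <- as.logical(toupper(flag))
  if (anyNA(flag)) {
    stop(sprintf("missing surface annotation for: %s",
                 paste(utils::head(proteins$accession[is.na(flag)], 10), collapse = ", ")),
         call. = FALSE)
  }
  unique(proteins$accession[flag])
}
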