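# Readers/writers for the plain-text dialects the pipeline exchanges.
# All tables are TSV: UTF-8, tab-separated, "." decimal, required header row.
# Unknown extra columns are preserved on round trip.

DECOY_PREFIX <- "REV_"

# -- low-level helpers --------------------------------------------------------

.read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("format error in %s: missing column(s) %s",
                 path, paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
}

# Coerce a character column to numeric, reporting the 1-based file line
# (header is line 1) of the first offending row.
.as_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value %s in column '%s' of %s (line %d)",
                 sQuote(x[bad[1L]]), col, path, bad[1L] + 1L), call. = FALSE)
  }
  out
}

.check_rows <- function(ok, col, path, what) {
  bad <- which(!ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid value in column '%s' of %s (line %d): %s",
                 col, path, bad[1L] + 1L, what), call. = FALSE)
  }
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE, scientific = FALSE))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

PSM_COLUMNS <- c("spectrum_id", "peptide", "proteins", "ion_score",
                 "parent_error_da", "fragment_error_da", "missed_cleavages",
                 "charge", "probability")

# -- PSM tables ---------------------------------------------------------------

#' Read a table of peptide-spectrum matches
#'
#' Parses the tab-separated PSM export dialect (one row per peptide-spectrum
#' match) and enforces field invariants on load. The `proteins` column is a
#' semicolon-joined list of accessions; a PSM is flagged as a decoy
#' (reverse-database) match iff *all* its accessions carry the `REV_` prefix,
#' mirroring composite forward+reverse database searching.
#'
#' @param path Path to a TSV file with columns `spectrum_id`, `peptide`,
#'   `proteins`, `ion_score`, `parent_error_da`, `fragment_error_da`,
#'   `missed_cleavages`, `charge`, `probability`. Extra columns are preserved.
#' @return Data frame with the dialect columns typed, an `is_decoy` logical
#'   column derived from the accession prefix, and any extra columns.
#' @export
read_psm_table <- function(path) {
  df <- .read_tsv_raw(path)
  .require_columns(df, PSM_COLUMNS, path)
  if (nrow(df) == 0L) {
    out <- df
    out$is_decoy <- logical(0)
    return(.retype_psms(out))
  }
  for (col in c("ion_score", "parent_error_da", "fragment_error_da", "probability")) {
    df[[col]] <- .as_numeric_col(df[[col]], col, path)
  }
  for (col in c("missed_cleavages", "charge")) {
    v <- .as_numeric_col(df[[col]], col, path)
    .check_rows(v == round(v), col, path, "must be an integer")
    df[[col]] <- as.integer(v)
  }
  .check_rows(nzchar(df$peptide) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$peptide),
              "peptide", path, "must be a non-empty canonical amino-acid string")
  .check_rows(nzchar(df$proteins), "proteins", path, "must list at least one accession")
  .check_rows(df$ion_score >= 0, "ion_score", path, "must be >= 0")
  .check_rows(df$fragment_error_da >= 0, "fragment_error_da", path, "must be >= 0")
  .check_rows(df$missed_cleavages >= 0L, "missed_cleavages", path, "must be >= 0")
  .check_rows(df$charge %in% 2:4, "charge", path, "must be one of 2, 3, 4")
  .check_rows(df$probability >= 0 & df$probability <= 1, "probability", path,
              "must be in [0, 1]")
  acc <- strsplit(df$proteins, ";", fixed = TRUE)
  df$is_decoy <- vapply(acc, function(a) all(startsWith(a, DECOY_PREFIX)), logical(1))
  df
}

.retype_psms <- function(df) {
  for (col in c("ion_score", "parent_error_da", "fragment_error_da", "probability")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("missed_cleavages", "charge")) df[[col]] <- as.integer(df[[col]])
  df
}

#' Write a PSM table in the exchange dialect
#'
#' Inverse of [read_psm_table()]; the derived `is_decoy` column is dropped
#' (it is recomputed from accession prefixes on read), every other column,
#' including unknown extras, is written.
#'
#' @param psms Data frame as returned by [read_psm_table()] or
#'   [generate_psm_table()].
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  stopifnot(is.data.frame(psms))
  psms$is_decoy <- NULL
  extras <- setdiff(names(psms), PSM_COLUMNS)
  .write_tsv(psms[c(PSM_COLUMNS, extras)], path)
}

# -- FASTA --------------------------------------------------------------------

#' Read a protein FASTA file
#'
#' The accession is the first whitespace-delimited token after `>`;
#' sequences are uppercased and whitespace-stripped. Letters outside the
#' 20-letter canonical alphabet are rejected, except the ambiguity code `X`,
#' which is allowed (such proteins are later excluded from molecular-weight
#' analysis).
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `accession` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(accession = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  aa <- Biostrings::readBStringSet(path)
  accession <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L,
                      USE.NAMES = FALSE)
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate accession in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  sequence <- unname(toupper(gsub("\\s", "", as.character(aa))))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    stop(sprintf("non-amino-acid letters in record(s): %s",
                 paste(accession[bad], collapse = ", ")), call. = FALSE)
  }
  data.frame(accession = accession, sequence = sequence, stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#' @param proteins Data frame with columns `accession` and `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(stats::setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# -- MS1 ion features ---------------------------------------------------------

#' Read an MS1 ion-feature table
#'
#' One row per extracted MS1 ion: m/z, charge, retention time (min),
#' intensity, and an optional peptide assignment (empty string when the ion
#' was not matched to an identified peptide).
#'
#' @param path Path to a TSV with columns `mz`, `charge`, `rt_min`,
#'   `intensity`, `peptide`.
#' @return Typed data frame.
#' @export
read_ion_table <- function(path) {
  df <- .read_tsv_raw(path)
  .require_columns(df, c("mz", "charge", "rt_min", "intensity", "peptide"), path)
  if (nrow(df) == 0L) {
    df$mz <- numeric(0); df$charge <- integer(0)
    df$rt_min <- numeric(0); df$intensity <- numeric(0)
    return(df)
  }
  for (col in c("mz", "rt_min", "intensity")) {
    df[[col]] <- .as_numeric_col(df[[col]], col, path)
  }
  v <- .as_numeric_col(df$charge, "charge", path)
  .check_rows(v == round(v) & v >= 1, "charge", path, "must be an integer >= 1")
  df$charge <- as.integer(v)
  .check_rows(df$mz > 0, "mz", path, "must be > 0")
  .check_rows(df$rt_min >= 0, "rt_min", path, "must be >= 0")
  .check_rows(is.finite(df$intensity) & df$intensity >= 0, "intensity", path,
              "must be finite and >= 0")
  df
}

#' Write an MS1 ion-feature table
#' @param ions Data frame as from [read_ion_table()].
#' @param path Output path.
#' @export
write_ion_table <- function(ions, path) {
  cols <- c("mz", "charge", "rt_min", "intensity", "peptide")
  .write_tsv(ions[c(cols, setdiff(names(ions), cols))], path)
}

# -- edge lists, catalogs, traces, generic mappings ---------------------------

#' Read a protein-protein interaction edge list
#'
#' @param path TSV with columns `protein_a`, `protein_b`; one undirected
#'   edge per row.
#' @return Data frame of edges (duplicates preserved; deduplication of
#'   unordered pairs happens in [count_interactions()]).
#' @export
read_edge_list <- function(path) {
  df <- .read_tsv_raw(path)
  .require_columns(df, c("protein_a", "protein_b"), path)
  if (nrow(df) > 0L) {
    .check_rows(nzchar(df$protein_a), "protein_a", path, "must be non-empty")
    .check_rows(nzchar(df$protein_b), "protein_b", path, "must be non-empty")
  }
  df
}

#' Write a protein-protein interaction edge list
#' @param edges Data frame with columns `protein_a`, `protein_b`.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) .write_tsv(edges, path)

#' Read an identifier catalog
#'
#' A catalog is one identifier per row (e.g. marker family symbols or
#' accessions of a reference proteome), with an optional `category` column.
#' Duplicate identifiers are collapsed to set semantics; the number dropped
#' is reported via a message.
#'
#' @param path TSV with column `identifier` and optionally `category`.
#' @return Data frame with column `identifier` (unique) and, if present,
#'   `category`.
#' @export
read_catalog <- function(path) {
  df <- .read_tsv_raw(path)
  .require_columns(df, "identifier", path)
  if (nrow(df) > 0L) .check_rows(nzchar(df$identifier), "identifier", path,
                                 "must be non-empty")
  key <- if ("category" %in% names(df)) paste(df$identifier, df$category) else df$identifier
  ndup <- sum(duplicated(key))
  if (ndup > 0L) {
    message(sprintf("read_catalog: dropped %d duplicate entr%s from %s",
                    ndup, if (ndup == 1L) "y" else "ies", path))
    df <- df[!duplicated(key), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write an identifier catalog
#' @param catalog Data frame with column `identifier` (and optionally
#'   `category`).
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) .write_tsv(catalog, path)

#' Read an MRM trace table
#'
#' A trace is the flat list of (m/z, intensity) points recorded while
#' monitoring one precursor in SRM/MRM mode.
#'
#' @param path TSV with columns `mz`, `intensity`.
#' @return Typed data frame.
#' @export
read_trace_table <- function(path) {
  df <- .read_tsv_raw(path)
  .require_columns(df, c("mz", "intensity"), path)
  if (nrow(df) == 0L) {
    df$mz <- numeric(0); df$intensity <- numeric(0)
    return(df)
  }
  df$mz <- .as_numeric_col(df$mz, "mz", path)
  df$intensity <- .as_numeric_col(df$intensity, "intensity", path)
  .check_rows(df$mz > 0, "mz", path, "must be > 0")
  .check_rows(is.finite(df$intensity) & df$intensity >= 0, "intensity", path,
              "must be finite and >= 0")
  df
}

#' Write an MRM trace table
#' @param trace Data frame with columns `mz`, `intensity`.
#' @param path Output path.
#' @export
write_trace_table <- function(trace, path) .write_tsv(trace, path)

#' Read a peptide-to-protein mapping
#' @param path TSV with columns `peptide`, `accession` (one row per link;
#'   shared peptides have several rows).
#' @return Data frame.
#' @export
read_peptide_map <- function(path) {
  df <- .read_tsv_raw(path)
  .require_columns(df, c("peptide", "accession"), path)
  df
}

#' Write a peptide-to-protein mapping
#' @param map Data frame with columns `peptide`, `accession`.
#' @param path Output path.
#' @export
write_peptide_map <- function(map, path) .write_tsv(map, path)
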