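# Shared fixtures and independent oracles, built in code at test time.

# A small, fully explicit PSM table covering both decoy conventions and
# values on either side of every filter gate.
make_psms <- function(score = c(50, 50, 41, 39, 50, 50),
                      decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                      parent = 0.05, fragment = 0.1, missed = 0L, prob = 0.95,
                      charge = 2L) {
  n <- length(score)
  acc <- ifelse(decoy, sprintf("REV_P%03d", seq_len(n)), sprintf("P%03d", seq_len(n)))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  i <- seq_len(n) - 1L
  data.frame(
    spectrum_id = sprintf("S%03d", seq_len(n)),
    peptide = paste0("PEPT", aa[i %% 20L + 1L], aa[i %/% 20L %% 20L + 1L], "K"),
    proteins = acc,
    ion_score = score,
    parent_error_da = rep_len(parent, n),
    fragment_error_da = rep_len(fragment, n),
    missed_cleavages = as.integer(rep_len(missed, n)),
    charge = as.integer(rep_len(charge, n)),
    probability = rep_len(prob, n),
    is_decoy = decoy,
    stringsAsFactors = FALSE)
}

# Random PSM table for property tests: every field straddles its gate,
# dense enough that some PSMs survive the full cascade.
random_psms <- function(n, seed) {
  set.seed(seed)
  make_psms(
    score = round(runif(n, 0, 80), 2),
    decoy = runif(n) < 0.4,
    parent = round(runif(n, -0.15, 0.15), 4),
    fragment = round(runif(n, 0, 0.3), 4),
    missed = sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    prob = round(runif(n, 0.7, 1), 4),
    charge = sample(2:4, n, replace = TRUE))
}

# Independent brute-force oracle for the constrained threshold search:
# plain enumeration with none of the package's selection machinery.
oracle_optimize <- function(psms, fpr_max, grid) {
  rows <- lapply(sort(unique(grid)), function(s) {
    keep <- psms$ion_score > s &
      abs(psms$parent_error_da) < 0.1 &
      psms$fragment_error_da < 0.2 &
      psms$missed_cleavages <= 1 &
      psms$probability >= 0.9
    r <- psms[keep, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    n_rev <- sum(r$is_decoy)
    n_fwd <- nrow(r) - n_rev
    fwd <- r[!r$is_decoy, , drop = FALSE]
    data.frame(s = s, n_pep = length(unique(paste(fwd$peptide, fwd$charge))),
               n_fwd = n_fwd, n_rev = n_rev,
               fpr = min(1, 2 * n_rev / nrow(r)))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(NULL)
  feas <- rows[rows$fpr <= fpr_max, , drop = FALSE]
  if (nrow(feas) > 0L) {
    feas <- feas[order(-feas$n_pep, feas$fpr, -feas$s), , drop = FALSE]
    cbind(feas[1L, ], constraint_met = TRUE)
  } else {
    rows <- rows[order(rows$fpr, -rows$s), , drop = FALSE]
    cbind(rows[1L, ], constraint_met = FALSE)
  }
}

# Brute-force interaction counter: double loop over all surface pairs.
oracle_interactions <- function(emv, target, edges) {
  edge_keys <- unique(apply(cbind(edges$protein_a, edges$protein_b), 1L,
                            function(e) paste(sort(e), collapse = "\r")))
  n_int <- 0L
  emv_part <- character(0)
  target_part <- character(0)
  for (x in unique(emv)) for (y in unique(target)) {
    if (paste(sort(c(x, y)), collapse = "\r") %in% edge_keys) {
      n_int <- n_int + 1L
      emv_part <- union(emv_part, x)
      target_part <- union(target_part, y)
    }
  }
  list(n_emv_partnered = length(emv_part),
       n_target_partnered = length(target_part), n_interactions = n_int)
}

# Average-mass oracle values frozen from an independent mass calculator
# (20 random sequences, fixed generation seed).
MW_ORACLE <- data.frame(
  sequence = c(
    "ICHDCGPNHMMDNLDPWHAVTHQLRVWTFCYQCKHWQVWWSHGYGCFTMPPCHHCRESCY",
    "LHQFCGMPAAFRVIGPFGENGTPWKPKFAGIAWFN",
    "VMKRSWVKDHER",
    "WPSFVLVLHDKCRGTLWSMEWCECFVVIHKSCPLLYRFAIAPCDRHKW",
    "LPGSPMPQVDWGPPTDNWLEQYRMIITVVSTTE",
    "CDAEALFSTYGRGKGMCGALMPPMYWRQRVALHYKPW",
    "QDHWAGISNDRW",
    "WYWEVGHIQVEFQHNFDWFIFCADCGQCKKEVSQTQHFENNQEC",
    "PLLELCKQCITRHWRWTNIGQGEIIVSCRMIIKAETCE",
    "QPSGMWCHNRVEQISMGRYFS",
    "ARSRLQDSFWIAQPSKPH",
    "HCWDAVELPVSDWMKKSHDSQQWLQEFTGGAYYSPSSLQTGSEMLYSQVV",
    "LHDRWGYMRRPMGCDVPWKRDQLKIRQVEAIWRDATCKEPTYDTISSQEVTGWGD",
    "ITMELTWQKWVSSSCRQRCLMLFESDPQLPLICDFSIHAMSEIDCVA",
    "MWMYLNFDVPKCWLGPDVTRT",
    "WAGQTCPA",
    "NHQVQHSTSFAWFRPYSADIEY",
    "QQKCIESCFKTTQKHANK",
    "CPMSQRMYFEWAVMFVPGWSIGMQGTLCSWEFVQPCGLDCTQKSQLN",
    "WWCKFLFSQQNFHSKYELK"),
  mass_da = c(
    7321.325946, 3893.504927, 1570.819714, 5808.880166, 3759.228603,
    4292.028285, 1484.533426, 5439.928411, 4473.301723, 2513.835059,
    2124.364885, 5738.277516, 6582.372151, 5463.363818, 2573.023462,
    832.924685, 2683.846405, 2122.431329, 5422.294880, 2519.878404),
  stringsAsFactors = FALSE)

write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
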