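# Translation of exon segments and peptide composition / charge profiling.

#' Translate a coding nucleotide segment
#'
#' Skips `phase` nucleotides at the segment start (the part of a codon
#' carried over from the previous exon), translates complete codons with the
#' standard genetic code, and drops any trailing partial codon. An internal
#' stop truncates the translation with a warning.
#'
#' @param nt coding nucleotide string.
#' @param phase nt to skip at the start: 0, 1 or 2.
#' @return one-row tibble: `peptide`, `n_skipped`, `n_trailing`
#'   (nt dropped at the end), `internal_stop`.
#' @export
translate_segment <- function(nt, phase = 0) {
  if (!phase %in% 0:2) {
    abort_spliceselect("phase must be 0, 1 or 2", "spliceselect_parameter_error")
  }
  nt <- normalize_seq(nt)
  body <- substr(nt, phase + 1, nchar(nt))
  if (nchar(body) < 3) {
    abort_spliceselect("fewer than one complete codon after phase trimming",
                       "spliceselect_validation_error")
  }
  n_codons <- nchar(body) %/% 3
  n_trailing <- nchar(body) %% 3
  codons <- substring(body, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing ambiguity symbols
  internal_stop <- FALSE
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    internal_stop <- TRUE
    aa <- aa[seq_len(stop_at[1] - 1)]
    rlang::warn(sprintf("internal stop codon at codon %d; translation truncated", stop_at[1]))
  }
  tibble::tibble(
    peptide = paste(aa, collapse = ""),
    n_skipped = as.integer(phase),
    n_trailing = as.integer(n_trailing),
    internal_stop = internal_stop
  )
}

#' Composition and charge profile of a peptide
#'
#' Counts residues, serines, charged residues under an explicit charge
#' convention (histidine counts as positive by default), and locates
#' phosphorylatable S/T/Y positions. Unknown symbols are tallied separately
#' and excluded from the charge classes.
#'
#' @param aa amino-acid string (single-letter, uppercase).
#' @param positive_set residues counted as positive (default K, R, H).
#' @param negative_set residues counted as negative (default D, E).
#' @return one-row tibble: `sequence`, `length`, `serine_count`,
#'   `positive_count`, `negative_count`, `net_charge`, `n_unknown`, plus
#'   list-columns `composition` (named counts) and `sty_positions`
#'   (1-based S/T/Y positions).
#' @export
profile_peptide <- function(aa, positive_set = c("K", "R", "H"),
                            negative_set = c("D", "E")) {
  aa <- toupper(aa)
  if (!nzchar(aa)) {
    abort_spliceselect("empty peptide", "spliceselect_validation_error")
  }
  residues <- strsplit(aa, "", fixed = TRUE)[[1]]
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  comp <- table(factor(residues, levels = aa20))
  n_unknown <- sum(!residues %in% aa20)
  pos <- sum(residues %in% positive_set)
  neg <- sum(residues %in% negative_set)
  tibble::tibble(
    sequence = aa,
    length = length(residues),
    serine_count = as.integer(comp[["S"]]),
    positive_count = pos,
    negative_count = neg,
    net_charge = pos - neg,
    n_unknown = n_unknown,
    composition = list(stats::setNames(as.integer(comp), aa20)),
    sty_positions = list(which(residues %in% c("S", "T", "Y")))
  )
}
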