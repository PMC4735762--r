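# Bundled reference tables: the human chromosome-22 donor-site PWM, the
# 14-species USP4 donor panel, and the human USP4 exon-7 peptide.

#' Human chromosome 22 donor-site PWM (published log-odds scores)
#'
#' A 13-column position weight matrix for 5' splice sites (5 exonic positions
#' -5..-1, 8 intronic positions +1..+8) derived from 15,770 exon-intron
#' junctions of human chromosome 22 protein-coding genes, shipped as
#' published log-odds scores (no underlying counts). Its consensus over
#' -3..+6 is `CAG|GTAAGT` (rendered `CAG|GUAAGU` in RNA).
#'
#' @return a scores-only `splice_pwm` (see [pwm_from_scores()]).
#' @export
chr22_donor_pwm <- function() {
  path <- system.file("extdata", "chr22_donor_pwm.tsv", package = "spliceselect",
                      mustWork = TRUE)
  pwm <- read_pwm_tsv(path)
  pwm$position_labels <- c(-5:-1, 1:8)
  pwm
}

#' USP4 donor-site panel for 14 vertebrate species
#'
#' Upstream (5'SS_6, donor of the intron before cassette exon 7) and
#' downstream (5'SS_7, the cassette exon's own donor) 13-mer junctions with
#' their published PWMS values, for 14 representative vertebrates, plus the
#' observed exon-7 skipping status (`alternative`, `constitutive`, or
#' `constitutive_inferred` where never directly assayed). Published PWMS
#' values are carried as data: they were computed with a wider scoring
#' window than the 13 printed matrix columns and are not reproducible from
#' [chr22_donor_pwm()] (identical 13-mers carry different published scores).
#'
#' @return tibble: `species`, `group`, `exon_present`, `ss6`, `pwms6`,
#'   `ss7`, `pwms7`, `observed_skipping`.
#' @export
usp4_donor_panel <- function() {
  path <- system.file("extdata", "usp4_donor_panel.tsv", package = "spliceselect",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Human USP4 exon-7 peptide
#'
#' The serine-rich linker peptide encoded by the cassette exon of human USP4,
#' as published (note: the published string has 48 letters though it is
#' described as 47 residues; the string is taken as given).
#'
#' @return a single amino-acid string.
#' @export
usp4_e7_peptide <- function() {
  "RSSTAPSRNFTTSPKSSASPYSSVSASLIANGDSTSTCGMHSSGVSRG"
}
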