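# Cassette-exon skipping prediction from donor-site +6 identities
# (primary rule) or from the PWMS difference of the flanking donors
# (secondary rule).
#
# Rationale for the class-based +6 rule: observed configurations show that
# skipping needs a strong-or-neutral upstream +6 (T or C) together with a
# weak downstream +6 (A or G); a strict ordinal comparison would miscall the
# zebrafish T-vs-C configuration, which retains the exon.

PLUS6_ORDER <- c(T = 3L, C = 2L, A = 1L, G = 0L)
PLUS6_STRONG_NEUTRAL <- c("T", "C")
PLUS6_WEAK <- c("A", "G")

#' Ordinal strength of a donor +6 nucleotide
#'
#' The sixth intronic nucleotide of a 5' splice site ranks T > C >= A > G:
#' +6T is optimal, +6C neutral, +6A and +6G weaken the site.
#'
#' @param base character vector of bases (U accepted as T).
#' @return integer vector: T=3, C=2, A=1, G=0.
#' @export
plus6_strength <- function(base) {
  base <- normalize_seq(base)
  bad <- !base %in% names(PLUS6_ORDER)
  if (any(bad)) {
    abort_spliceselect(sprintf("invalid +6 base: %s", base[bad][1]),
                       "spliceselect_invalid_base_error")
  }
  unname(PLUS6_ORDER[base])
}

#' Predict cassette-exon skipping from the +6 configuration
#'
#' The discriminant rule: an exon is called `alternative_skipping` when the
#' upstream donor's +6 is strong or neutral (T or C) and the cassette exon's
#' own (downstream) donor +6 is weak (A or G); any other configuration is
#' `constitutive_retention`. Exons absent from the annotation are
#' `exon_lost`.
#'
#' @param upstream_plus6,downstream_plus6 +6 bases of the upstream and
#'   downstream donors (vectors recycle together).
#' @param exon_present logical; `FALSE` forces `exon_lost`.
#' @return tibble: `call`, `rule` (`"plus6"`), `detail`.
#' @export
predict_from_plus6 <- function(upstream_plus6, downstream_plus6, exon_present = TRUE) {
  n <- max(length(upstream_plus6), length(downstream_plus6), length(exon_present))
  up <- rep_len(normalize_seq(upstream_plus6), n)
  dn <- rep_len(normalize_seq(downstream_plus6), n)
  present <- rep_len(exon_present, n)
  plus6_strength(c(up, dn))  # validates
  call <- ifelse(
    !present, "exon_lost",
    ifelse(up %in% PLUS6_STRONG_NEUTRAL & dn %in% PLUS6_WEAK,
           "alternative_skipping", "constitutive_retention")
  )
  tibble::tibble(
    call = call,
    rule = "plus6",
    detail = ifelse(
      !present, "exon absent from annotation",
      sprintf("upstream +6%s (%s) vs downstream +6%s (%s)",
              up, ifelse(up %in% PLUS6_STRONG_NEUTRAL, "strong/neutral", "weak"),
              dn, ifelse(dn %in% PLUS6_WEAK, "weak", "strong/neutral"))
    )
  )
}

#' Predict skipping from the PWMS difference of the flanking donors
#'
#' Secondary criterion: a markedly stronger upstream donor
#' (`upstream - downstream > delta_threshold`) favours skipping.
#'
#' @param upstream_pwms,downstream_pwms numeric PWMS vectors.
#' @param delta_threshold score-difference threshold (default 2; a package
#'   calibration, not a published constant).
#' @param exon_present logical; `FALSE` forces `exon_lost`.
#' @return tibble: `call`, `rule` (`"pwms_delta"`), `detail`.
#' @export
predict_from_pwms <- function(upstream_pwms, downstream_pwms,
                              delta_threshold = 2, exon_present = TRUE) {
  n <- max(length(upstream_pwms), length(downstream_pwms), length(exon_present))
  up <- rep_len(upstream_pwms, n)
  dn <- rep_len(downstream_pwms, n)
  present <- rep_len(exon_present, n)
  if (any(present & (!is.finite(up) | !is.finite(dn)))) {
    abort_spliceselect("PWMS values must be finite for annotated exons",
                       "spliceselect_insufficient_evidence_error")
  }
  delta <- up - dn
  tibble::tibble(
    call = ifelse(!present, "exon_lost",
                  ifelse(delta > delta_threshold, "alternative_skipping",
                         "constitutive_retention")),
    rule = "pwms_delta",
    detail = ifelse(!present, "exon absent from annotation",
                    sprintf("PWMS delta %.4f vs threshold %.4f", delta, delta_threshold))
  )
}

# +6 base of a donor junction string: 6th intronic nt. A "|" marker, if
# present, defines the boundary; otherwise exon_flank does.
plus6_of <- function(site, exon_flank = 5) {
  site <- toupper(site)
  boundary <- ifelse(grepl("|", site, fixed = TRUE),
                     regexpr("|", site, fixed = TRUE) - 1L,
                     exon_flank)
  normalize_seq(substr(gsub("|", "", site, fixed = TRUE), boundary + 6L, boundary + 6L))
}

#' Classify a species panel of donor configurations
#'
#' Applies [predict_from_plus6()] (or [predict_from_pwms()]) to a panel of
#' species, extracting +6 identities from donor 13-mers when explicit
#' `upstream_plus6`/`downstream_plus6` columns are absent. Donor strings may
#' carry a `|` exon-intron marker. When a `pwm` is supplied, PWMS values are
#' (re)computed from the site strings with [score_sequence()]; otherwise
#' existing `pwms6`/`pwms7` columns are used for the `pwms_delta` rule.
#'
#' @param panel tibble with columns `species`, `group` (optional),
#'   `exon_present`, and either `upstream_plus6`/`downstream_plus6` or donor
#'   site strings `ss6`/`ss7`.
#' @param rule `"plus6"` (default) or `"pwms_delta"`.
#' @param pwm optional `splice_pwm` for on-the-fly scoring.
#' @param delta_threshold threshold for the `pwms_delta` rule.
#' @param exon_flank exonic flank width of the site strings (default 5).
#' @return the panel with `call`, `rule`, `detail` columns appended, plus a
#'   `"summary"` attribute tabulating calls per group.
#' @export
classify_panel <- function(panel, rule = c("plus6", "pwms_delta"), pwm = NULL,
                           delta_threshold = 2, exon_flank = 5) {
  rule <- match.arg(rule)
  if (nrow(panel) == 0) {
    return(structure(dplyr::mutate(panel, call = character(), rule = character(),
                                   detail = character()),
                     summary = tibble::tibble()))
  }
  present <- if ("exon_present" %in% names(panel)) panel$exon_present else TRUE
  if (!"upstream_plus6" %in% names(panel) && "ss6" %in% names(panel)) {
    panel$upstream_plus6 <- plus6_of(panel$ss6, exon_flank)
    panel$downstream_plus6 <- ifelse(rep_len(present, nrow(panel)),
                                     plus6_of(panel$ss7, exon_flank), NA)
  }
  if (!is.null(pwm)) {
    strip <- function(x) normalize_seq(gsub("|", "", x, fixed = TRUE))
    panel$pwms6 <- score_sequences(pwm, strip(panel$ss6))$score
    panel$pwms7 <- score_sequences(pwm, strip(panel$ss7))$score
  }
  res <- if (rule == "plus6") {
    up <- panel$upstream_plus6
    dn <- ifelse(is.na(panel$downstream_plus6), "A", panel$downstream_plus6)
    predict_from_plus6(up, dn, present)
  } else {
    predict_from_pwms(panel$pwms6, panel$pwms7, delta_threshold, present)
  }
  out <- dplyr::bind_cols(panel, res)
  summ <- if ("group" %in% names(out)) {
    dplyr::count(out, .data$group, .data$call)
  } else {
    dplyr::count(out, .data$call)
  }
  structure(out, summary = summ)
}

#' Plot a classified panel
#'
#' Tile plot of +6 configurations coloured by the resulting call.
#'
#' @param calls tibble from [classify_panel()] under the `plus6` rule.
#' @return a ggplot object.
#' @export
plot_skipping_calls <- function(calls) {
  calls$label <- sprintf("+6%s / +6%s", calls$upstream_plus6, calls$downstream_plus6)
  ggplot2::ggplot(calls, ggplot2::aes(x = 1, y = stats::reorder(.data$species, seq_len(nrow(calls))),
                                      fill = .data$call, label = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
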