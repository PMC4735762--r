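# Branchpoint (YURAY) detection: motif scanning, the intervening-AG
# exclusion rule, distances to the intron 3' end, and the optimal-distance
# window used to call a strong branchpoint.

# YURAY in DNA rendering: [CT]T[AG]A[CT]. Note the motif itself can never
# contain an AG dinucleotide (positions are Y,T,R,A,Y and R-A pairs are
# followed by Y), so AG exclusion needs no overlap special-casing.
YURAY_REGEX <- "(?=([CT]T[AG]A[CT]))"

#' Scan an intron for YURAY branchpoint motifs
#'
#' Reports every (possibly overlapping) occurrence of the degenerate
#' branchpoint consensus Y-U-R-A-Y (`[CT]T[AG]A[CT]` on the DNA alphabet).
#'
#' @param intron_seq intron nucleotide string (U accepted).
#' @return tibble: `start` (0-based offset), `motif` (5-nt string).
#' @export
scan_yuray <- function(intron_seq) {
  intron_seq <- normalize_seq(intron_seq)
  m <- gregexpr(YURAY_REGEX, intron_seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(start = integer(), motif = character()))
  }
  starts <- as.integer(m)
  tibble::tibble(
    start = starts - 1L,
    motif = substring(intron_seq, starts, starts + 4L)
  )
}

#' Classify YURAY hits by the intervening-AG rule and 3'-end distance
#'
#' The first AG downstream of a genuine branchpoint is generally used as the
#' 3' splice-site AG, so a candidate motif is disqualified when a non-3'SS
#' AG dinucleotide starts anywhere between the end of the motif and the
#' terminal AG (offsets `start + 5 .. L - 3`, the 3'SS AG occupying
#' `L - 2, L - 1`). The distance to the 3' end is measured from the first
#' base of the motif: `d_to3 = L - start`, so a motif occupying the final
#' 5 nt has `d_to3 = 5`.
#'
#' @param intron_seq intron string; a warning is raised (and the terminal
#'   dinucleotide still treated as the 3'SS) if it does not end in AG.
#' @param hits tibble from [scan_yuray()]; scanned afresh when `NULL`.
#' @param window optional `c(lo, hi)` optimal-distance window; when given,
#'   an `in_opt_window` column is added.
#' @return tibble: `start`, `motif`, `d_to3`, `intervening_ag`,
#'   `is_candidate` (`!intervening_ag`), and optionally `in_opt_window`.
#' @export
classify_hits <- function(intron_seq, hits = NULL, window = NULL) {
  intron_seq <- normalize_seq(intron_seq)
  L <- nchar(intron_seq)
  if (L >= 2 && substr(intron_seq, L - 1, L) != "AG") {
    rlang::warn(sprintf("intron does not end in AG (ends in %s); treating terminal dinucleotide as the 3'SS",
                        substr(intron_seq, L - 1, L)))
  }
  if (is.null(hits)) hits <- scan_yuray(intron_seq)
  ag <- gregexpr("(?=AG)", intron_seq, perl = TRUE)[[1]]
  ag_starts0 <- if (ag[1] == -1) integer() else as.integer(ag) - 1L
  out <- tibble::tibble(
    start = hits$start,
    motif = hits$motif,
    d_to3 = L - hits$start,
    intervening_ag = vapply(hits$start, function(s) {
      any(ag_starts0 >= s + 5L & ag_starts0 <= L - 3L)
    }, logical(1))
  )
  out$is_candidate <- !out$intervening_ag
  if (!is.null(window)) {
    out$in_opt_window <- out$d_to3 >= window[1] & out$d_to3 <= window[2]
  }
  out
}

#' Estimate the optimal branchpoint distance window
#'
#' Finds the smallest contiguous integer window `[lo, hi]` of distances to
#' the 3' end that covers at least `coverage_target` of the observed values
#' (ties broken toward smaller `lo`). Applied genome-wide this recovers the
#' range where genuine branchpoints concentrate (about 20-40 nt upstream of
#' the acceptor in human).
#'
#' @param d_values integer vector of distances (>= 10 values).
#' @param coverage_target required fraction of values inside the window
#'   (default 0.75).
#' @param min_intron_length optional filter: `d_values` may carry an
#'   `intron_length` attribute or be a data frame with columns `d_to3` and
#'   `intron_length`; introns shorter than this are dropped before
#'   estimation (default `NULL`, no filter).
#' @return one-row tibble: `lo`, `hi`, `coverage`.
#' @export
estimate_opt_window <- function(d_values, coverage_target = 0.75,
                                min_intron_length = NULL) {
  if (is.data.frame(d_values)) {
    if (!is.null(min_intron_length)) {
      d_values <- d_values[d_values$intron_length >= min_intron_length, ]
    }
    d_values <- d_values$d_to3
  }
  d_values <- as.integer(d_values)
  n <- length(d_values)
  if (n < 10) {
    abort_spliceselect("need at least 10 distance values", "spliceselect_estimation_error")
  }
  if (coverage_target <= 0 || coverage_target > 1) {
    abort_spliceselect("coverage_target must be in (0, 1]", "spliceselect_validation_error")
  }
  d <- sort(d_values)
  k <- ceiling(coverage_target * n)
  # among all windows spanning k order statistics, take the narrowest;
  # ties go to the smallest lower bound
  lo_cand <- d[seq_len(n - k + 1)]
  hi_cand <- d[seq_len(n - k + 1) + k - 1]
  widths <- hi_cand - lo_cand
  best <- which(widths == min(widths))[1]
  lo <- lo_cand[best]
  hi <- hi_cand[best]
  tibble::tibble(lo = as.integer(lo), hi = as.integer(hi),
                 coverage = mean(d_values >= lo & d_values <= hi))
}

#' Call a strong branchpoint in an intron
#'
#' An intron has a strong branchpoint when at least one clean YURAY motif
#' (no intervening AG) lies with its distance-to-3'-end inside the optimal
#' window. The best hit is the candidate closest to the window midpoint
#' (ties toward the smaller distance).
#'
#' @param intron_seq intron string.
#' @param window a `c(lo, hi)` pair or one-row tibble from
#'   [estimate_opt_window()].
#' @return list with `strong` (logical) and `best` (one-row tibble of the
#'   best in-window candidate, or `NULL`).
#' @export
call_strong_bps <- function(intron_seq, window) {
  if (is.data.frame(window)) window <- c(window$lo[1], window$hi[1])
  hits <- classify_hits(intron_seq, window = window)
  cand <- hits[hits$is_candidate & hits$in_opt_window, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(strong = FALSE, best = NULL))
  }
  mid <- mean(window)
  cand <- cand[order(abs(cand$d_to3 - mid), cand$d_to3), ]
  list(strong = TRUE, best = cand[1, ])
}

#' Branchpoint calls for every intron of a gene model panel
#'
#' @param introns tibble with columns `gene_id` (optional), `intron_index`
#'   (or `index`) and `seq`; e.g. [derive_introns()] output.
#' @param window optimal-distance window `c(lo, hi)` (default `c(20, 40)`,
#'   the genome-wide human estimate).
#' @param tail_n scan only the last `tail_n` nt of each intron
#'   (default 50, matching how branchpoint maps are drawn; `Inf` scans all).
#' @return tibble: one row per intron with `strong_bps`, `best_d_to3`,
#'   `best_motif`, `n_candidates`.
#' @export
call_bps_panel <- function(introns, window = c(20, 40), tail_n = 50) {
  idx_col <- if ("intron_index" %in% names(introns)) "intron_index" else "index"
  purrr::map_dfr(seq_len(nrow(introns)), function(i) {
    s <- normalize_seq(introns$seq[i])
    if (is.finite(tail_n) && nchar(s) > tail_n) {
      s <- substr(s, nchar(s) - tail_n + 1, nchar(s))
    }
    res <- call_strong_bps(s, window)
    hits <- classify_hits(s, window = window)
    tibble::tibble(
      gene_id = if ("gene_id" %in% names(introns)) introns$gene_id[i] else NA_character_,
      intron_index = introns[[idx_col]][i],
      intron_length = nchar(normalize_seq(introns$seq[i])),
      strong_bps = res$strong,
      best_d_to3 = if (res$strong) res$best$d_to3 else NA_integer_,
      best_motif = if (res$strong) res$best$motif else NA_character_,
      n_candidates = sum(hits$is_candidate & hits$in_opt_window)
    )
  })
}

#' Histogram data of branchpoint distances
#'
#' Distance-to-3'-end values of clean YURAY motifs across a set of introns,
#' for drawing the genome-wide distance distribution.
#'
#' @param intron_seqs character vector of intron sequences.
#' @param min_intron_length drop introns shorter than this before counting
#'   (default 200, avoiding the statistical bias short introns introduce).
#' @param candidates_only keep only motifs with no intervening AG
#'   (default TRUE).
#' @return tibble: `intron` (index into input), `d_to3`, `motif`.
#' @export
bps_distance_table <- function(intron_seqs, min_intron_length = 200,
                               candidates_only = TRUE) {
  keep <- which(nchar(intron_seqs) >= min_intron_length)
  purrr::map_dfr(keep, function(i) {
    h <- suppressWarnings(classify_hits(intron_seqs[i]))
    if (candidates_only) h <- h[h$is_candidate, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    tibble::tibble(intron = i, d_to3 = h$d_to3, motif = h$motif)
  })
}

#' Plot the branchpoint distance distribution
#'
#' @param d_table tibble from [bps_distance_table()].
#' @param window optional `c(lo, hi)` window drawn as a shaded band.
#' @return a ggplot object.
#' @export
plot_bps_distances <- function(d_table, window = NULL) {
  p <- ggplot2::ggplot(d_table, ggplot2::aes(x = .data$d_to3)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey30") +
    ggplot2::labs(x = "distance from YURAY start to intron 3' end (nt)",
                  y = "motif count") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}
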