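# Position weight matrices for splice-site strength: construction from
# junction sets, log-odds (PWMS) scoring, consensus, information content,
# and the paired comparison of site-strength samples.

#' Build a position weight matrix from aligned junction sequences
#'
#' Counts per-position base occurrences over a set of equal-length junction
#' strings and converts them to log2 odds against a background:
#' \deqn{score(b, j) = \log_2 \frac{(n_{bj} + s\,q_b)/(n + s)}{q_b}}
#' where \eqn{n_{bj}} is the count of base \eqn{b} at position \eqn{j},
#' \eqn{n} the number of junctions, \eqn{q_b} the background probability and
#' \eqn{s} the pseudocount. With pseudocount 0, zero-probability cells are
#' floored at `score_floor` instead of \eqn{-\infty}. Ambiguity symbols
#' contribute to no base's count.
#'
#' @param junctions character vector (>= 2) of equal-length junction strings
#'   (RNA `U` accepted, normalized to `T`).
#' @param position_labels optional integer/character labels, one per column
#'   (e.g. `-5..-1, 1..8` for a donor with 5 exonic and 8 intronic nt).
#' @param background `"uniform"` or a named per-base probability vector
#'   summing to 1 with no zero entries.
#' @param pseudocount non-negative scalar pseudocount (default 1).
#' @param score_floor value replacing non-finite log odds when
#'   `pseudocount = 0` (default -30; preserves ordering without infinities).
#' @return an object of class `splice_pwm` with elements `alphabet`,
#'   `position_labels`, `counts` (4 x width), `background`, `pseudocount`,
#'   `n`, `probs` (pseudocounted frequencies) and `scores`.
#' @export
build_pwm <- function(junctions, position_labels = NULL, background = "uniform",
                      pseudocount = 1, score_floor = -30) {
  junctions <- normalize_seq(junctions)
  if (length(junctions) < 2) {
    abort_spliceselect("need at least 2 junction sequences", "spliceselect_validation_error")
  }
  w <- unique(nchar(junctions))
  if (length(w) != 1) {
    abort_spliceselect("junction sequences must all have the same length",
                       "spliceselect_shape_error")
  }
  if (is.null(position_labels)) position_labels <- seq_len(w)
  if (length(position_labels) != w) {
    abort_spliceselect("position_labels length must equal junction width",
                       "spliceselect_shape_error")
  }
  background <- resolve_background(background)

  chars <- matrix(unlist(strsplit(junctions, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(junctions), byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    as.integer(tab)
  }, integer(4))
  dimnames(counts) <- list(DNA_BASES, as.character(position_labels))

  n <- length(junctions)
  probs <- sweep(counts + pseudocount * background, 2, rep(n + pseudocount, w), "/")
  scores <- log2(sweep(probs, 1, background, "/"))
  scores[!is.finite(scores)] <- score_floor

  structure(
    list(alphabet = DNA_BASES, position_labels = position_labels,
         counts = counts, background = background, pseudocount = pseudocount,
         n = n, probs = probs, scores = scores),
    class = "splice_pwm"
  )
}

resolve_background <- function(background) {
  if (identical(background, "uniform")) {
    background <- stats::setNames(rep(0.25, 4), DNA_BASES)
  }
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0)) {
    abort_spliceselect("background must give a positive probability to each of A, C, G, T",
                       "spliceselect_background_error")
  }
  if (abs(sum(background) - 1) > 1e-8) {
    abort_spliceselect("background probabilities must sum to 1",
                       "spliceselect_background_error")
  }
  background
}

#' Assemble a PWM object directly from a score matrix
#'
#' For matrices published as log-odds scores without underlying counts
#' (scoring-only use: [score_sequence()], [pwm_consensus()], [max_score()]).
#'
#' @param scores 4 x width numeric matrix with rownames A, C, G, T (or U).
#' @param position_labels labels, one per column; defaults to colnames.
#' @return a `splice_pwm` with `counts`, `probs`, `n` set to `NA`.
#' @export
pwm_from_scores <- function(scores, position_labels = colnames(scores)) {
  rn <- chartr("U", "T", toupper(rownames(scores)))
  scores <- scores[match(DNA_BASES, rn), , drop = FALSE]
  rownames(scores) <- DNA_BASES
  structure(
    list(alphabet = DNA_BASES, position_labels = position_labels,
         counts = NULL, background = stats::setNames(rep(0.25, 4), DNA_BASES),
         pseudocount = NA_real_, n = NA_integer_, probs = NULL,
         scores = scores),
    class = "splice_pwm"
  )
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf("<splice_pwm> width %d%s\n", ncol(x$scores),
              if (!is.na(x$n)) sprintf(", built from %d junctions (pseudocount %g)", x$n, x$pseudocount) else " (scores only)"))
  print(round(x$scores, 4))
  invisible(x)
}

pwm_width <- function(pwm) ncol(pwm$scores)

#' Score a junction sequence against a PWM (PWMS)
#'
#' The PWMS is the sum of per-position log-odds lookups. Symbols outside
#' A/C/G/T (ambiguity codes) contribute 0 at their position.
#'
#' @param pwm a `splice_pwm`.
#' @param junction junction string of the PWM's width (U accepted).
#' @return a one-row tibble: `sequence`, `score`, and
#'   `per_position_contributions` (list-column of per-position values whose
#'   sum equals `score`).
#' @export
score_sequence <- function(pwm, junction) {
  junction <- normalize_seq(junction)
  w <- pwm_width(pwm)
  if (nchar(junction) != w) {
    abort_spliceselect(
      sprintf("junction length %d does not match PWM width %d", nchar(junction), w),
      "spliceselect_shape_error"
    )
  }
  bases <- strsplit(junction, "", fixed = TRUE)[[1]]
  idx <- match(bases, DNA_BASES)
  contrib <- ifelse(is.na(idx), 0, pwm$scores[cbind(idx, seq_len(w))])
  tibble::tibble(
    sequence = junction,
    score = sum(contrib),
    per_position_contributions = list(as.numeric(contrib))
  )
}

#' Score many junction sequences
#'
#' @param pwm a `splice_pwm`.
#' @param junctions character vector of junction strings.
#' @return tibble with one row per junction (see [score_sequence()]).
#' @export
score_sequences <- function(pwm, junctions) {
  purrr::map_dfr(junctions, score_sequence, pwm = pwm)
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax base (by score), with ties broken alphabetically and
#' flagged.
#'
#' @param pwm a `splice_pwm`.
#' @return the consensus string, with attribute `ties`: logical vector
#'   marking positions where two or more bases share the maximum.
#' @export
pwm_consensus <- function(pwm) {
  s <- pwm$scores
  best <- apply(s, 2, function(col) DNA_BASES[which.max(col)])
  ties <- apply(s, 2, function(col) sum(col == max(col)) > 1)
  structure(paste(best, collapse = ""), ties = unname(ties))
}

#' Maximum attainable PWMS
#'
#' Sum of per-position score maxima; the score of the consensus sequence.
#'
#' @param pwm a `splice_pwm`.
#' @return numeric scalar.
#' @export
max_score <- function(pwm) {
  sum(apply(pwm$scores, 2, max))
}

#' Per-position information content (bits)
#'
#' \eqn{I_j = \log_2 4 - H_j} of the (pseudocounted) column frequencies; the
#' per-base logo heights are `freq * I_j`.
#'
#' @param pwm a `splice_pwm` built from counts.
#' @return tibble: `position` (label), `information` (bits), plus one column
#'   per base with its logo height.
#' @export
column_information <- function(pwm) {
  if (is.null(pwm$probs)) {
    abort_spliceselect("information content needs a counts-built PWM",
                       "spliceselect_validation_error")
  }
  p <- pwm$probs
  H <- apply(p, 2, function(col) -sum(ifelse(col > 0, col * log2(col), 0)))
  info <- log2(4) - H
  heights <- sweep(p, 2, info, "*")
  out <- tibble::tibble(position = pwm$position_labels, information = unname(info))
  for (b in DNA_BASES) out[[b]] <- unname(heights[b, ])
  out
}

#' Paired comparison of splice-site strength samples
#'
#' Classical two-sided paired t-test on per-gene score differences (e.g.,
#' upstream vs downstream donor PWMS across species). A zero-variance
#' difference sample is reported as degenerate: `t` is 0 when the mean
#' difference is 0, otherwise signed infinity, with `degenerate = TRUE`.
#'
#' @param score_a,score_b equal-length numeric vectors of paired scores.
#' @return one-row tibble: `n_pairs`, `mean_diff`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `degenerate`.
#' @export
paired_pwms_test <- function(score_a, score_b) {
  if (length(score_a) != length(score_b)) {
    abort_spliceselect("paired samples must have equal length", "spliceselect_shape_error")
  }
  n <- length(score_a)
  if (n < 2) {
    abort_spliceselect("need at least 2 pairs", "spliceselect_validation_error")
  }
  d <- score_a - score_b
  md <- mean(d)
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      n_pairs = n, mean_diff = md,
      t_statistic = if (md == 0) 0 else sign(md) * Inf,
      degrees_of_freedom = n - 1L,
      p_value = if (md == 0) 1 else 0,
      degenerate = TRUE
    ))
  }
  tt <- stats::t.test(score_a, score_b, paired = TRUE)
  tibble::tibble(
    n_pairs = n, mean_diff = md,
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = as.integer(unname(tt$parameter)),
    p_value = tt$p.value,
    degenerate = FALSE
  )
}

#' Tidy a PWM into a long tibble
#'
#' @param x a `splice_pwm`.
#' @param ... unused.
#' @return tibble: `position`, `base`, `score`, and when counts are
#'   available also `count` and `freq`.
#' @exportS3Method generics::tidy
tidy.splice_pwm <- function(x, ...) {
  w <- pwm_width(x)
  out <- tibble::tibble(
    position = rep(x$position_labels, each = 4),
    base = rep(DNA_BASES, w),
    score = as.numeric(x$scores)
  )
  if (!is.null(x$counts)) {
    out$count <- as.integer(x$counts)
    out$freq <- as.numeric(x$probs)
  }
  out
}

#' One-row summary of a PWM
#'
#' @param x a `splice_pwm`.
#' @param ... unused.
#' @return tibble: `width`, `n`, `pseudocount`, `max_score`, `consensus`.
#' @exportS3Method generics::glance
glance.splice_pwm <- function(x, ...) {
  tibble::tibble(
    width = pwm_width(x), n = x$n, pseudocount = x$pseudocount,
    max_score = max_score(x), consensus = as.character(pwm_consensus(x))
  )
}

#' Sequence-logo style plot of a PWM
#'
#' Stacked per-base information heights (bits) by position; a text-based
#' logo analogue drawn with ggplot2.
#'
#' @param object a counts-built `splice_pwm`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.splice_pwm <- function(object, ...) {
  info <- column_information(object)
  long <- tidyr::pivot_longer(info, cols = dplyr::all_of(DNA_BASES),
                              names_to = "base", values_to = "height")
  long$position <- factor(long$position, levels = unique(info$position))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$height,
                                     fill = .data$base, label = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::labs(x = "position", y = "information (bits)", fill = "base") +
    ggplot2::theme_minimal()
}

#' Write / read a PWM as TSV with a JSON sidecar
#'
#' The TSV holds the score matrix (rows = bases, header = position labels);
#' `<path>.json` records background, pseudocount and training-set size.
#'
#' @param pwm a `splice_pwm`.
#' @param path TSV path.
#' @return `path` invisibly (writer); a `splice_pwm` (reader).
#' @export
write_pwm_tsv <- function(pwm, path) {
  df <- as.data.frame(pwm$scores)
  colnames(df) <- as.character(pwm$position_labels)
  df <- cbind(base = rownames(pwm$scores), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  jsonlite::write_json(
    list(background = as.list(pwm$background), pseudocount = pwm$pseudocount, n = pwm$n),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_pwm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$base
  labels <- colnames(df)[-1]
  labels <- suppressWarnings(ifelse(is.na(as.integer(labels)), labels, as.integer(labels)))
  pwm <- pwm_from_scores(m, position_labels = labels)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pwm$background <- stats::setNames(as.numeric(meta$background[DNA_BASES]), DNA_BASES)
    pwm$pseudocount <- meta$pseudocount
    pwm$n <- meta$n
  }
  pwm
}
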