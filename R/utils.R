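# Internal sequence and interval helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts RNA `U` to `T`. Ambiguity codes and other symbols
#' are retained verbatim; downstream scoring treats them as background and
#' motif matching never accepts them.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector, same length as `x`.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA strings (normalized alphabet).
#' @return character vector of reverse complements. Non-ACGT symbols are
#'   left unchanged (but still reversed).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGT", "TGCA", normalize_seq(s))
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n <= 0) {
    return(c(lo = NA_real_, hi = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

# substring over 0-based half-open coordinates (vectorized over positions)
substr0 <- function(x, start0, end0) {
  substring(x, start0 + 1L, end0)
}

abort_spliceselect <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "spliceselect_error"), ...)
}

`%||%` <- rlang::`%||%`
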