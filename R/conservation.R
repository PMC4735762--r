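# Sequence conservation: Shannon entropy over protein alignment columns
# (with sliding-window smoothing) and exon/intron length architecture
# summaries across species groups.

#' Shannon entropy of one alignment column
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the observed residue counts, with
#' \eqn{p_i} = count / total. Gap symbols must already be excluded from
#' `counts`. A column with no counted states (all gaps) yields `NA`, not 0.
#'
#' @param counts non-negative integer vector of per-residue counts.
#' @param n_states alphabet size, the entropy ceiling \eqn{\log_2 N}
#'   (20 for protein; informational only, not used in the formula).
#' @return entropy in bits.
#' @export
column_entropy <- function(counts, n_states = 20) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(NA_real_)
  }
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Read an aligned FASTA into an aligned block
#'
#' @param path aligned FASTA (protein) path.
#' @param groups optional named vector mapping sequence ids to clade labels.
#' @return tibble: `id`, `group`, `seq` (equal-length aligned rows).
#' @export
read_aligned_fasta <- function(path, groups = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- tibble::tibble(
    id = ids,
    group = if (is.null(groups)) NA_character_ else unname(groups[ids]),
    seq = toupper(as.character(ss))
  )
  validate_aligned_block(out)
  out
}

validate_aligned_block <- function(block) {
  if (nrow(block) < 2) {
    abort_spliceselect("an aligned block needs at least 2 sequences",
                       "spliceselect_validation_error")
  }
  if (length(unique(nchar(block$seq))) != 1) {
    abort_spliceselect("aligned sequences must all have the same length",
                       "spliceselect_shape_error")
  }
  invisible(block)
}

#' Per-column entropy profile of a protein alignment
#'
#' Computes Shannon entropy (bits) for each alignment column over non-gap
#' residues, masks columns whose non-gap coverage falls below
#' `min_coverage`, and smooths with a centred moving average over the
#' unmasked columns inside an odd `window`.
#'
#' @param block tibble with a `seq` column of equal-length aligned protein
#'   strings (gap symbol `-`; `.` and `X` are also treated as non-residues),
#'   e.g. from [read_aligned_fasta()].
#' @param window odd smoothing window in columns (default 9).
#' @param min_coverage minimum non-gap fraction for a column to enter the
#'   profile (default 0.5).
#' @return tibble: `column`, `H`, `smoothed_H`, `coverage`.
#' @export
entropy_profile <- function(block, window = 9, min_coverage = 0.5) {
  validate_aligned_block(block)
  width <- nchar(block$seq[1])
  if (window %% 2 == 0 || window < 1) {
    abort_spliceselect("window must be a positive odd integer", "spliceselect_parameter_error")
  }
  if (window > width) {
    abort_spliceselect("window exceeds alignment length", "spliceselect_parameter_error")
  }
  chars <- matrix(unlist(strsplit(block$seq, "", fixed = TRUE), use.names = FALSE),
                  nrow = nrow(block), byrow = TRUE)
  non_residue <- c("-", ".", "X", "*")
  H <- numeric(width)
  coverage <- numeric(width)
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[!col %in% non_residue]
    coverage[j] <- length(col) / nrow(block)
    H[j] <- if (length(col)) column_entropy(table(col)) else NA_real_
  }
  H[coverage < min_coverage] <- NA_real_
  half <- (window - 1) / 2
  smoothed <- vapply(seq_len(width), function(j) {
    win <- H[max(1, j - half):min(width, j + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(column = seq_len(width), H = H, smoothed_H = smoothed,
                 coverage = coverage)
}

#' Plot an entropy profile
#'
#' @param profile tibble from [entropy_profile()].
#' @return a ggplot object (per-column entropy in grey, smoothed in black).
#' @export
plot_entropy_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$column)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$H), colour = "grey70", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_H), colour = "black", na.rm = TRUE) +
    ggplot2::labs(x = "alignment column", y = "Shannon entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Length-architecture summaries per clade and unit
#'
#' Summarizes exon or intron lengths per (group, unit, index) cell: the
#' modal length (smallest on ties), the fraction of the group at the mode,
#' and the observed range.
#'
#' @param lengths tibble with columns `species`, `group`, `unit`
#'   (`"exon"`/`"intron"`), `index`, `length`.
#' @return tibble: `group`, `unit`, `index`, `n`, `mode`, `mode_fraction`,
#'   `min`, `max`.
#' @export
length_summaries <- function(lengths) {
  lengths |>
    dplyr::group_by(.data$group, .data$unit, .data$index) |>
    dplyr::summarise(
      n = dplyr::n(),
      mode = {
        tab <- table(.data$length)
        as.integer(names(tab)[tab == max(tab)][1])
      },
      mode_fraction = max(table(.data$length)) / dplyr::n(),
      min = min(.data$length),
      max = max(.data$length),
      .groups = "drop"
    )
}
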