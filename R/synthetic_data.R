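# Seeded generators: donor junction sets drawn from a known probability
# matrix, multi-exon gene models with planted donor +6 identities and
# branchpoints, and junction-spanning reads with a known inclusion
# fraction. Every generator returns a machine-readable truth record; tests
# read ground truth only from there.

#' Per-position probability matrix concentrated on a consensus
#'
#' Convenience truth matrix for the donor generator: the consensus base gets
#' probability `p` at each position, the other three split the remainder.
#'
#' @param consensus consensus string (U accepted).
#' @param p consensus-base probability per position (default 0.7).
#' @return 4 x width matrix with rownames A, C, G, T, columns summing to 1.
#' @export
consensus_prob_matrix <- function(consensus, p = 0.7) {
  bases <- strsplit(normalize_seq(consensus), "", fixed = TRUE)[[1]]
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- p
  m
}

#' Sample donor junction strings from a probability matrix
#'
#' Independent per-position sampling; reproducible per seed.
#'
#' @param pwm_truth 4 x width probability matrix (rownames A, C, G, T;
#'   columns sum to 1).
#' @param n number of junctions.
#' @param seed RNG seed.
#' @return character vector of `n` junction strings, with the truth matrix
#'   attached as attribute `truth`.
#' @export
sample_donors <- function(pwm_truth, n, seed = 1) {
  stopifnot(nrow(pwm_truth) == 4)
  if (any(abs(colSums(pwm_truth) - 1) > 1e-8) || any(pwm_truth < 0)) {
    abort_spliceselect("pwm_truth columns must be probabilities summing to 1",
                       "spliceselect_validation_error")
  }
  w <- ncol(pwm_truth)
  seqs <- withr::with_seed(seed, {
    cols <- lapply(seq_len(w), function(j) {
      sample(DNA_BASES, n, replace = TRUE, prob = pwm_truth[, j])
    })
    do.call(paste0, cols)
  })
  structure(seqs, truth = pwm_truth)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Plant splice landmarks into a random intron: GT..AG boundaries, the +6
# identity, an optional clean YURAY at a requested distance from the 3'
# end, AG exclusion between motif and 3'SS, and purging of accidental
# clean YURAYs in the scan window. Deterministic fix-ups with an iteration
# cap keep planted truth exact.
build_intron <- function(L, plus6, d_to3 = NA, purge_window = 50, max_iter = 1000) {
  if (!is.na(d_to3) && (d_to3 < 7 || d_to3 > L - 2)) {
    abort_spliceselect(
      sprintf("planted branchpoint distance %d infeasible in a %d-nt intron", d_to3, L),
      "spliceselect_config_error"
    )
  }
  ch <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
  ch[1:2] <- c("G", "T")
  if (!is.na(plus6)) ch[6] <- plus6
  ch[(L - 1):L] <- c("A", "G")
  planted_start0 <- NA_integer_
  if (!is.na(d_to3)) {
    planted_start0 <- L - d_to3
    ch[(planted_start0 + 1):(planted_start0 + 5)] <- c("C", "T", "A", "A", "C")
  }
  win_lo0 <- max(0L, L - as.integer(purge_window))  # purge only near the 3' end
  for (iter in seq_len(max_iter)) {
    s <- paste(ch, collapse = "")
    changed <- FALSE
    # non-3'SS AG between planted motif (or window start) and the 3'SS
    ag_from0 <- if (!is.na(planted_start0)) planted_start0 + 5L else win_lo0
    ag <- gregexpr("(?=AG)", s, perl = TRUE)[[1]]
    ag0 <- if (ag[1] == -1) integer() else as.integer(ag) - 1L
    bad_ag <- ag0[ag0 >= ag_from0 & ag0 <= L - 3L]
    if (length(bad_ag)) {
      ch[bad_ag[1] + 2L] <- "C"  # mutate the G; predecessor is A, no new AG
      changed <- TRUE
    }
    # accidental clean YURAYs in the scan window (other than the planted one)
    if (!changed) {
      hits <- scan_yuray(s)
      stray <- hits$start[hits$start >= win_lo0 & hits$start <= L - 5L]
      if (!is.na(planted_start0)) stray <- setdiff(stray, planted_start0)
      stray <- stray[stray != 0L]  # never touch the GT boundary region
      if (length(stray)) {
        ch[stray[1] + 2L] <- "G"  # kill the central T; predecessor is Y, no new AG
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (changed) {
    abort_spliceselect("could not purge intron within iteration cap",
                       "spliceselect_config_error")
  }
  list(seq = paste(ch, collapse = ""), planted_start0 = planted_start0)
}

#' Generate a synthetic gene model with planted splice signals
#'
#' Builds a multi-exon gene on random background sequence with canonical
#' GT..AG introns, requested donor +6 identities, and optionally planted
#' clean YURAY branchpoints at chosen distances from each intron's 3' end.
#' Within the 3'-terminal scan window, accidental clean YURAY motifs and
#' non-3'SS AG dinucleotides are purged so the planted configuration is the
#' exact ground truth. Defaults emulate a mammal-like cassette architecture:
#' three exons (cassette exon of 144 nt), an upstream donor with +6T, the
#' cassette exon's own donor with +6A, a strong branchpoint 30 nt from the
#' 3' end of the downstream intron, and none in the upstream intron.
#'
#' @param exon_lengths integer vector (>= 3 exons by default;
#'   `c(150, 144, 150)`).
#' @param intron_lengths integer vector, one per intron (`c(500, 300)`).
#' @param plus6 donor +6 base per intron, `NA` = leave random
#'   (`c("T", "A")`).
#' @param bps_plan tibble with columns `intron_index`, `d_to3` of planted
#'   clean branchpoints (default: one at d = 30 in intron 2). Introns not
#'   listed get their scan window purged of clean YURAYs.
#' @param purge_window 3'-terminal window (nt) kept free of stray signals
#'   (default 50).
#' @param cassette_index which exon is the cassette exon (default 2).
#' @param gene_id,species labels for the model.
#' @param seed RNG seed.
#' @return list with `gene_model` (a [gene_model()]) and `truth` (seed,
#'   lengths, `plus6`, planted branchpoints with realized 0-based starts,
#'   `cassette_index`, and `expected_call` under the +6 class rule).
#' @export
synth_gene_model <- function(exon_lengths = c(150, 144, 150),
                             intron_lengths = c(500, 300),
                             plus6 = c("T", "A"),
                             bps_plan = tibble::tibble(intron_index = 2, d_to3 = 30),
                             purge_window = 50,
                             cassette_index = 2,
                             gene_id = "synthetic_gene", species = "synthetic",
                             seed = 1) {
  k <- length(exon_lengths)
  if (k < 2 || length(intron_lengths) != k - 1) {
    abort_spliceselect("need n exons and n-1 introns (n >= 2)", "spliceselect_config_error")
  }
  plus6 <- rep_len(normalize_seq(plus6), k - 1)
  withr::with_seed(seed, {
    exon_seqs <- vapply(exon_lengths, random_dna, character(1))
    intron_info <- lapply(seq_len(k - 1), function(i) {
      d <- bps_plan$d_to3[bps_plan$intron_index == i]
      build_intron(intron_lengths[i], plus6[i],
                   d_to3 = if (length(d)) d[1] else NA,
                   purge_window = purge_window)
    })
  })
  intron_seqs <- vapply(intron_info, `[[`, character(1), "seq")
  pieces <- character(2 * k - 1)
  pieces[seq(1, 2 * k - 1, 2)] <- exon_seqs
  pieces[seq(2, 2 * k - 2, 2)] <- intron_seqs
  sequence <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  starts <- cumsum(c(0, lens[-length(lens)]))
  exon_rows <- seq(1, 2 * k - 1, 2)
  gm <- gene_model(gene_id,
                   tibble::tibble(start = starts[exon_rows],
                                  end = starts[exon_rows] + lens[exon_rows]),
                   sequence, species = species)
  planted <- tibble::tibble(
    intron_index = seq_len(k - 1),
    start0 = vapply(intron_info, function(x) as.integer(x$planted_start0 %||% NA_integer_), integer(1)),
    d_to3 = intron_lengths - vapply(intron_info, function(x) as.integer(x$planted_start0 %||% NA_integer_), integer(1))
  )
  planted <- planted[!is.na(planted$start0), ]
  expected_call <- NA_character_
  if (k >= 3 && cassette_index >= 2 && cassette_index < k) {
    up <- plus6[cassette_index - 1]
    dn <- plus6[cassette_index]
    expected_call <- if (!is.na(up) && !is.na(dn) &&
                         up %in% c("T", "C") && dn %in% c("A", "G")) {
      "alternative_skipping"
    } else {
      "constitutive_retention"
    }
  }
  list(
    gene_model = gm,
    truth = list(seed = seed, exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths), plus6 = plus6,
                 planted_bps = planted, purge_window = purge_window,
                 cassette_index = cassette_index, expected_call = expected_call)
  )
}

#' Simulate junction-spanning reads from a cassette-exon gene
#'
#' Each read is drawn from the exon-retained transcript with probability
#' `psi`, otherwise from the cassette-skipped transcript, with a uniform
#' start position and independent per-base substitution errors.
#'
#' @param gm a [gene_model()] with >= 3 exons.
#' @param cassette_index the cassette exon (default 2).
#' @param psi inclusion fraction in `[0, 1]` (default 0.7).
#' @param n number of reads (default 2000).
#' @param read_len read length (default 80).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed RNG seed.
#' @return list with `reads` (tibble: `read_id`, `seq`, `origin`) and
#'   `truth` (psi, n, read_len, error_rate, transcript lengths, seed).
#' @export
synth_reads <- function(gm, cassette_index = 2, psi = 0.7, n = 2000,
                        read_len = 80, error_rate = 0, seed = 1) {
  k <- n_exons(gm)
  if (k < 3 || cassette_index < 2 || cassette_index >= k) {
    abort_spliceselect("need an internal cassette exon", "spliceselect_config_error")
  }
  exons <- vapply(seq_len(k), exon_seq, character(1), gm = gm)
  retained <- paste(exons, collapse = "")
  skipped <- paste(exons[-cassette_index], collapse = "")
  if (read_len > nchar(skipped)) {
    abort_spliceselect("read_len exceeds the skipped transcript length",
                       "spliceselect_config_error")
  }
  reads <- withr::with_seed(seed, {
    origin <- ifelse(stats::runif(n) < psi, "retained", "skipped")
    seqs <- character(n)
    for (o in c("retained", "skipped")) {
      idx <- which(origin == o)
      if (!length(idx)) next
      tx <- if (o == "retained") retained else skipped
      s0 <- sample.int(nchar(tx) - read_len + 1L, length(idx), replace = TRUE) - 1L
      seqs[idx] <- substr0(tx, s0, s0 + read_len)
    }
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(ch)) < error_rate)
        for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble::tibble(read_id = sprintf("read_%05d", seq_len(n)), seq = seqs,
                   origin = origin)
  })
  list(
    reads = reads,
    truth = list(psi = psi, n = n, read_len = read_len, error_rate = error_rate,
                 retained_length = nchar(retained), skipped_length = nchar(skipped),
                 cassette_index = cassette_index, seed = seed)
  )
}

#' Write simulated reads as FASTQ
#'
#' Constant maximum quality; byte-identical for identical inputs.
#'
#' @param reads tibble from [synth_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}
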