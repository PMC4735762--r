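# Shared fixtures and independent oracles used across test files.

# Deterministic toy gene: 3 exons on a 60-nt region.
# exons (0,10), (20,30), (45,60); introns of length 10 and 15 (GT..AG).
toy_sequence <- function() {
  paste0(
    "ACGTACGTAC",      # exon 1  (0,10)
    "GTAAGTCAAG",      # intron 1 (10,20)
    "CCCCCAGGTT",      # exon 2  (20,30)
    "GTTTTCTAACGCTAG", # intron 2 (30,45)
    "GGGCCCAAATTTCCC"  # exon 3  (45,60)
  )
}

toy_gene <- function(strand = "+") {
  gene_model("toygene",
             tibble::tibble(start = c(0, 20, 45), end = c(10, 30, 60)),
             toy_sequence(), species = "Testus exemplaris", strand = strand)
}

# Minimal GFF3 + FASTA encoding of a plus-strand gene model.
write_toy_gff3 <- function(gm, gff_path, fasta_path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttest\tgene\t1\t%d\t.\t+\t.\tID=gene1", gm$gene_id, nchar(gm$sequence)),
    sprintf("%s\ttest\tmRNA\t1\t%d\t.\t+\t.\tID=t1;Parent=gene1", gm$gene_id, nchar(gm$sequence)),
    sprintf("%s\ttest\texon\t%d\t%d\t.\t+\t.\tParent=t1",
            gm$gene_id, gm$exons$start + 1L, gm$exons$end)
  )
  writeLines(lines, gff_path)
  writeLines(c(paste0(">", gm$gene_id), gm$sequence), fasta_path)
  invisible(gff_path)
}

# Random multi-exon gene built from explicit pieces (independent of the
# package's synthetic generator) for reconstruction/round-trip properties.
random_piece_gene <- function(n_exons, seed) {
  withr::with_seed(seed, {
    exon_lens <- sample(20:60, n_exons, replace = TRUE)
    intron_lens <- sample(30:80, n_exons - 1, replace = TRUE)
    pieces <- character(2 * n_exons - 1)
    for (i in seq_along(pieces)) {
      len <- if (i %% 2 == 1) exon_lens[(i + 1) / 2] else intron_lens[i / 2]
      pieces[i] <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
    }
    lens <- nchar(pieces)
    starts <- cumsum(c(0, lens[-length(lens)]))
    exon_idx <- seq(1, 2 * n_exons - 1, 2)
    list(
      gm = gene_model(paste0("rand", seed),
                      tibble::tibble(start = starts[exon_idx],
                                     end = starts[exon_idx] + lens[exon_idx]),
                      paste(pieces, collapse = "")),
      pieces = pieces
    )
  })
}

# --- independent oracles -----------------------------------------------------

# All 8 concrete YURAY strings (DNA alphabet).
yuray_strings <- function() {
  out <- character()
  for (y1 in c("C", "T")) for (r in c("A", "G")) for (y2 in c("C", "T")) {
    out <- c(out, paste0(y1, "T", r, "A", y2))
  }
  out
}

# Brute-force YURAY scan: enumerate every offset, compare substrings.
brute_yuray <- function(s) {
  L <- nchar(s)
  if (L < 5) return(tibble::tibble(start = integer(), motif = character()))
  starts1 <- seq_len(L - 4)
  subs <- substring(s, starts1, starts1 + 4)
  keep <- subs %in% yuray_strings()
  tibble::tibble(start = starts1[keep] - 1L, motif = subs[keep])
}

# Brute-force classification: literal AG search between motif end and the
# terminal 3'SS AG.
brute_classify <- function(s) {
  L <- nchar(s)
  hits <- brute_yuray(s)
  hits$d_to3 <- L - hits$start
  hits$intervening_ag <- vapply(hits$start, function(st) {
    if (st + 5L > L - 3L) return(FALSE)
    offs <- seq(st + 5L, L - 3L)
    any(substring(s, offs + 1L, offs + 2L) == "AG")
  }, logical(1))
  hits$is_candidate <- !hits$intervening_ag
  hits
}

# Brute-force strong-branchpoint call.
brute_strong <- function(s, window) {
  h <- brute_classify(s)
  cand <- h[h$is_candidate & h$d_to3 >= window[1] & h$d_to3 <= window[2], ]
  nrow(cand) > 0
}

# Naive per-position PWM scoring loop (no matrix indexing tricks).
naive_pwms <- function(scores, junction) {
  bases <- strsplit(junction, "")[[1]]
  total <- 0
  for (j in seq_along(bases)) {
    if (bases[j] %in% rownames(scores)) {
      total <- total + scores[bases[j], j]
    }
  }
  total
}

random_intron_ending_ag <- function(len) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  paste0(substr(s, 1, len - 2), "AG")
}
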