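test_that("probe construction slices the exon flanks", {
  p <- build_probes("AAAA", "CCCC", "GGGG", flank = 2)
  expect_equal(p$seq[p$junction == "E6E7"], "AACC")
  expect_equal(p$seq[p$junction == "E7E8"], "CCGG")
  expect_equal(p$seq[p$junction == "E6E8"], "AAGG")
  expect_equal(p$class, c("retained", "retained", "skipped"))
  expect_true(all(nchar(p$seq) == 4))

  expect_error(build_probes("AAA", "CCCC", "GGGG", flank = 4),
               class = "spliceselect_parameter_error")

  withr::with_seed(31, {
    e <- vapply(1:3, function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    }, character(1))
  })
  p2 <- build_probes(e[1], e[2], e[3], flank = 12)
  expect_equal(p2$seq[1], paste0(substr(e[1], 29, 40), substr(e[2], 1, 12)))
  expect_equal(p2$seq[3], paste0(substr(e[1], 29, 40), substr(e[3], 1, 12)))
})

test_that("read classification enforces the overhang threshold", {
  p <- build_probes(strrep("A", 30), strrep("C", 30), strrep("G", 30),
                    flank = 20)
  # read containing the full skipped probe
  expect_equal(as.character(classify_read(paste0("TTTT", p$seq[3], "TTTT"), p)),
               "skipped")
  # read overlapping the E6-E7 junction by only 3 nt on the intron side
  short_overlap <- paste0(strrep("A", 30), "CCC")
  expect_equal(as.character(classify_read(short_overlap, p, min_overhang = 8)),
               "none")
  # exactly min_overhang on each side is enough
  exact <- paste0(strrep("A", 8), strrep("C", 8))
  expect_equal(as.character(classify_read(exact, p, min_overhang = 8)),
               "retained")
  # a read matching both classes is ambiguous
  both <- paste0(p$seq[1], "TTTT", p$seq[3])
  expect_equal(as.character(classify_read(both, p)), "ambiguous")
})

test_that("mismatch-tolerant matching degrades gracefully", {
  p <- build_probes(strrep("A", 30), strrep("C", 30), strrep("G", 30),
                    flank = 20)
  core <- paste0(strrep("A", 8), strrep("C", 8))
  mutated <- core
  substr(mutated, 4, 4) <- "G"
  expect_equal(as.character(classify_read(mutated, p, max_mismatch = 0)), "none")
  expect_equal(as.character(classify_read(mutated, p, max_mismatch = 1)),
               "retained")
})

test_that("counting conserves reads and is strand symmetric", {
  g <- synth_gene_model(seed = 3)
  sim <- synth_reads(g$gene_model, psi = 0.6, n = 800, seed = 12)
  ex <- vapply(1:3, function(i) {
    substring(g$gene_model$sequence, g$gene_model$exons$start[i] + 1,
              g$gene_model$exons$end[i])
  }, character(1))
  probes <- build_probes(ex[1], ex[2], ex[3], flank = 20)

  cs <- count_support(sim$reads$seq, probes)
  expect_equal(cs$retained + cs$skipped + cs$ambiguous + cs$unmatched,
               cs$total_scanned)
  expect_equal(cs$total_scanned, 800)

  cs_rc <- count_support(revcomp(sim$reads$seq), probes)
  expect_equal(cs_rc[, c("retained", "skipped", "ambiguous", "unmatched")],
               cs[, c("retained", "skipped", "ambiguous", "unmatched")])

  # error-free reads never support the isoform they did not come from
  skipped_origin <- sim$reads$seq[sim$reads$origin == "skipped"]
  cls <- vapply(skipped_origin, function(r) {
    as.character(classify_read(r, probes))
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(cls %in% c("skipped", "none")))
  retained_origin <- sim$reads$seq[sim$reads$origin == "retained"]
  cls_r <- vapply(retained_origin, function(r) {
    as.character(classify_read(r, probes))
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(cls_r %in% c("retained", "none")))
})

test_that("PSI estimation recovers the planted inclusion fraction", {
  g <- synth_gene_model(seed = 5)
  ex <- vapply(1:3, function(i) {
    substring(g$gene_model$sequence, g$gene_model$exons$start[i] + 1,
              g$gene_model$exons$end[i])
  }, character(1))
  probes <- build_probes(ex[1], ex[2], ex[3], flank = 20)

  hits <- 0
  for (seed in 1:10) {
    sim <- synth_reads(g$gene_model, psi = 0.7, n = 2000, seed = seed)
    cs <- count_support(sim$reads$seq, probes,
                        transcript_lengths = c(retained = sim$truth$retained_length,
                                               skipped = sim$truth$skipped_length))
    if (cs$psi_lo <= 0.7 && 0.7 <= cs$psi_hi) hits <- hits + 1
  }
  expect_gte(hits, 8)

  # degenerate inputs
  none <- count_support(c("TTTTTTTTTTTTTTTTTT"), probes)
  expect_true(is.na(none$psi))
  expect_true(is.na(none$ratio_long_short))
})

test_that("the long-to-short ratio is the raw count quotient", {
  # counts chosen to mirror a typical isoform-ratio readout
  p <- build_probes(strrep("A", 30), strrep("C", 30), strrep("G", 30),
                    flank = 10)
  retained_read <- paste0(strrep("A", 10), strrep("C", 10))
  skipped_read <- paste0(strrep("A", 10), strrep("G", 10))
  reads <- c(rep(retained_read, 152), rep(skipped_read, 100))
  cs <- count_support(reads, p)
  expect_equal(cs$retained, 152)
  expect_equal(cs$skipped, 100)
  expect_equal(cs$ratio_long_short, 1.52)
})

test_that("FASTA/FASTQ inputs stream through the same counting path", {
  g <- synth_gene_model(seed = 9)
  sim <- synth_reads(g$gene_model, psi = 0.5, n = 200, seed = 2)
  ex <- vapply(1:3, function(i) {
    substring(g$gene_model$sequence, g$gene_model$exons$start[i] + 1,
              g$gene_model$exons$end[i])
  }, character(1))
  probes <- build_probes(ex[1], ex[2], ex[3], flank = 20)

  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(sim$reads, fq)
  from_file <- count_support(fq, probes)
  from_mem <- count_support(sim$reads$seq, probes)
  expect_equal(from_file, from_mem)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_probe_fasta(probes, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[[1]]), probes$seq[1])
})
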