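# Gene-model container, GenBank/GFF3 parsing, intron derivation and
# exon-intron junction extraction.
#
# Internal coordinates are 0-based half-open on a sequence stored in
# transcription orientation: minus-strand annotations are reverse-complemented
# and remapped at the parsing boundary so that exon order always equals
# transcription order.

#' Construct a gene model
#'
#' A `gene_model` holds one gene's exon coordinates and region sequence in
#' transcription orientation. Coordinates are 0-based half-open; for genes
#' annotated on the minus strand the sequence must already be
#' reverse-complemented (the readers do this) so that exon order is
#' transcription order.
#'
#' @param gene_id gene identifier.
#' @param exons a data frame (or matrix) with columns `start`, `end`
#'   (0-based half-open), sorted in transcription order, non-overlapping.
#' @param sequence nucleotide string covering all exons; normalized to the
#'   DNA alphabet internally.
#' @param species optional species label.
#' @param strand original annotation strand, `"+"` or `"-"`. Purely a
#'   provenance record: the stored sequence is always transcription-oriented.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, exons, sequence, species = "", strand = "+") {
  exons <- tibble::as_tibble(as.data.frame(exons))[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  sequence <- normalize_seq(sequence)
  if (!strand %in% c("+", "-")) {
    abort_spliceselect("strand must be '+' or '-'", "spliceselect_validation_error")
  }
  if (nrow(exons) < 1) {
    abort_spliceselect("a gene model needs at least one exon", "spliceselect_validation_error")
  }
  if (any(exons$end <= exons$start)) {
    bad <- which(exons$end <= exons$start)[1]
    abort_spliceselect(
      sprintf("exon %d has end <= start (%d, %d)", bad, exons$start[bad], exons$end[bad]),
      "spliceselect_validation_error"
    )
  }
  if (is.unsorted(exons$start, strictly = TRUE)) {
    abort_spliceselect("exons must be sorted in transcription order", "spliceselect_validation_error")
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    bad <- which(exons$start[-1] < exons$end[-nrow(exons)])[1]
    abort_spliceselect(
      sprintf("exons %d and %d overlap", bad, bad + 1),
      "spliceselect_validation_error"
    )
  }
  if (max(exons$end) > nchar(sequence)) {
    abort_spliceselect("exon coordinates exceed sequence length", "spliceselect_validation_error")
  }
  structure(
    list(gene_id = gene_id, species = species, strand = strand,
         exons = exons, sequence = sequence),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s%s  strand %s  %d exon(s), %d nt region\n",
              x$gene_id,
              if (nzchar(x$species)) paste0(" (", x$species, ")") else "",
              x$strand, nrow(x$exons), nchar(x$sequence)))
  print(x$exons, n = 10)
  invisible(x)
}

n_exons <- function(gm) nrow(gm$exons)

exon_seq <- function(gm, i) {
  substr0(gm$sequence, gm$exons$start[i], gm$exons$end[i])
}

#' Read an annotated gene record
#'
#' Parses a GenBank flat file, or a GFF3 file plus genome/region FASTA, into a
#' [gene_model()]. Minus-strand records are reverse-complemented and their
#' exon coordinates remapped so the returned model is transcription-oriented.
#' When several transcripts are annotated the longest (largest summed exon
#' length) is used unless `transcript` names one.
#'
#' @param path path to the GenBank or GFF3 file.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta for `format = "gff3"`, path to the FASTA holding the sequence
#'   the GFF3 coordinates refer to.
#' @param transcript optional transcript identifier selecting among multiple
#'   annotated transcripts.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(path, format = c("genbank", "gff3"), fasta = NULL,
                            transcript = NULL) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort_spliceselect(sprintf("unsupported format: %s", format[1]),
                       "spliceselect_format_error")
  })
  switch(format,
    genbank = read_gene_model_genbank(path, transcript = transcript),
    gff3 = read_gene_model_gff3(path, fasta = fasta, transcript = transcript)
  )
}

# ---- GenBank flat file (minimal, offline) -----------------------------------
# Supports the subset this package writes: LOCUS/ORGANISM headers, exon
# features with plain or complement(a..b) locations, optional /transcript_id
# qualifiers, and an ORIGIN sequence block.

read_gene_model_genbank <- function(path, transcript = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  gene_id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1] else "gene"
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  species <- if (length(org)) trimws(sub("^\\s+ORGANISM", "", org[1])) else ""

  # sequence block
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) {
    abort_spliceselect("GenBank record has no ORIGIN sequence block",
                       "spliceselect_parse_error")
  }
  seq_lines <- lines[(oi[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- normalize_seq(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # exon features
  feat_idx <- grep("^\\s{5}\\S", lines)
  feats <- list()
  for (k in seq_along(feat_idx)) {
    i <- feat_idx[k]
    stop_at <- if (k < length(feat_idx)) feat_idx[k + 1] - 1 else min(oi[1] - 1, length(lines))
    key <- strsplit(trimws(lines[i]), "\\s+")[[1]][1]
    if (!identical(key, "exon")) next
    block <- paste(trimws(lines[i:stop_at]), collapse = " ")
    loc <- sub("^exon\\s+", "", trimws(lines[i]))
    tid <- if (grepl("/transcript_id=", block)) {
      sub('.*?/transcript_id="([^"]+)".*', "\\1", block)
    } else "t1"
    feats[[length(feats) + 1]] <- list(loc = loc, tid = tid)
  }
  if (!length(feats)) {
    abort_spliceselect("GenBank record has no exon features",
                       "spliceselect_parse_error")
  }

  parse_loc <- function(loc) {
    comp <- grepl("^complement\\(", loc)
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    m <- regmatches(inner, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", inner))[[1]]
    if (length(m) != 3) {
      abort_spliceselect(sprintf("cannot parse exon location '%s'", loc),
                         "spliceselect_parse_error")
    }
    list(start1 = as.integer(m[2]), end1 = as.integer(m[3]), complement = comp)
  }
  parsed <- lapply(feats, function(f) c(parse_loc(f$loc), tid = f$tid))
  tids <- vapply(parsed, function(p) p$tid, character(1))
  pick <- select_transcript(tids, parsed, transcript)
  parsed <- parsed[pick]

  comp <- vapply(parsed, function(p) p$complement, logical(1))
  if (length(unique(comp)) != 1) {
    abort_spliceselect("exon features mix strands within one transcript",
                       "spliceselect_parse_error")
  }
  strand <- if (comp[1]) "-" else "+"
  exons <- tibble::tibble(
    start = vapply(parsed, function(p) p$start1, integer(1)) - 1L,
    end = vapply(parsed, function(p) p$end1, integer(1))
  )
  orient_model(gene_id, species, strand, exons, sequence)
}

select_transcript <- function(tids, parsed, transcript) {
  if (!is.null(transcript)) {
    pick <- which(tids == transcript)
    if (!length(pick)) {
      abort_spliceselect(sprintf("transcript '%s' not found", transcript),
                         "spliceselect_parse_error")
    }
    return(pick)
  }
  sizes <- tapply(
    vapply(parsed, function(p) p$end1 - p$start1 + 1L, integer(1)),
    tids, sum
  )
  which(tids == names(sizes)[which.max(sizes)])
}

# Flip a plus-strand-coordinate annotation into transcription orientation.
orient_model <- function(gene_id, species, strand, exons, sequence) {
  exons <- exons[order(exons$start), ]
  if (strand == "-") {
    L <- nchar(sequence)
    sequence <- revcomp(sequence)
    exons <- tibble::tibble(start = L - exons$end, end = L - exons$start)
    exons <- exons[order(exons$start), ]
  }
  gene_model(gene_id, exons, sequence, species = species, strand = strand)
}

read_gene_model_gff3 <- function(path, fasta, transcript = NULL) {
  if (is.null(fasta)) {
    abort_spliceselect("format 'gff3' needs a companion FASTA via `fasta`",
                       "spliceselect_parse_error")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) {
    abort_spliceselect("GFF3 file has no exon features", "spliceselect_parse_error")
  }
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p)) as.character(p[1]) else "t1"
  }, character(1))
  widths <- GenomicRanges::width(gr)
  pick <- if (!is.null(transcript)) {
    idx <- which(parents == transcript)
    if (!length(idx)) {
      abort_spliceselect(sprintf("transcript '%s' not found", transcript),
                         "spliceselect_parse_error")
    }
    idx
  } else {
    sizes <- tapply(widths, parents, sum)
    which(parents == names(sizes)[which.max(sizes)])
  }
  gr <- gr[pick]
  seqs <- Biostrings::readDNAStringSet(fasta)
  seqname <- as.character(GenomicRanges::seqnames(gr))[1]
  hit <- which(sub("\\s.*$", "", names(seqs)) == seqname)
  if (!length(hit)) {
    abort_spliceselect(sprintf("FASTA has no sequence named '%s'", seqname),
                       "spliceselect_parse_error")
  }
  sequence <- as.character(seqs[[hit[1]]])
  strand <- as.character(GenomicRanges::strand(gr))
  strand <- if (all(strand == "-")) "-" else "+"
  exons <- tibble::tibble(
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  gene_id <- seqname
  orient_model(gene_id, "", strand, exons, sequence)
}

#' Write a gene model as a GenBank-like flat file
#'
#' Emits the minimal GenBank subset [read_gene_model()] parses, so that
#' write/read round-trips reproduce exons, strand and sequence exactly.
#' Models recorded as minus-strand are written with `complement()` locations
#' over the reverse-complemented (plus-strand) sequence.
#'
#' @param gm a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_genbank <- function(gm, path) {
  L <- nchar(gm$sequence)
  if (gm$strand == "-") {
    sequence <- revcomp(gm$sequence)
    starts1 <- L - gm$exons$end + 1L
    ends1 <- L - gm$exons$start
    o <- order(starts1)
    locs <- sprintf("complement(%d..%d)", starts1[o], ends1[o])
  } else {
    sequence <- gm$sequence
    locs <- sprintf("%d..%d", gm$exons$start + 1L, gm$exons$end)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear", gm$gene_id, L), con)
  writeLines(sprintf("DEFINITION  %s gene region.", gm$gene_id), con)
  if (nzchar(gm$species)) {
    writeLines("SOURCE      .", con)
    writeLines(sprintf("  ORGANISM  %s", gm$species), con)
  }
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (loc in locs) {
    writeLines(sprintf("     exon            %s", loc), con)
  }
  writeLines("ORIGIN", con)
  chunks <- substring(tolower(sequence), seq(1, L, 60), pmin(seq(1, L, 60) + 59, L))
  for (i in seq_along(chunks)) {
    writeLines(sprintf("%9d %s", (i - 1) * 60 + 1, chunks[i]), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Derive introns from a gene model
#'
#' Intron `i` lies between exon `i` and exon `i + 1` (so the intron upstream
#' of cassette exon 7 is intron 6). Single-exon genes yield an empty table.
#'
#' @param gm a [gene_model()].
#' @return a tibble with one row per intron: `index`, `seq`, `length`,
#'   `donor_dinucleotide`, `acceptor_dinucleotide`.
#' @export
derive_introns <- function(gm) {
  k <- n_exons(gm)
  if (k < 2) {
    return(tibble::tibble(index = integer(), seq = character(), length = integer(),
                          donor_dinucleotide = character(),
                          acceptor_dinucleotide = character()))
  }
  starts <- gm$exons$end[-k]
  ends <- gm$exons$start[-1]
  if (any(ends - starts <= 0)) {
    bad <- which(ends - starts <= 0)[1]
    abort_spliceselect(
      sprintf("intron %d between adjacent exons has length %d", bad, ends[bad] - starts[bad]),
      "spliceselect_validation_error"
    )
  }
  seqs <- substr0(gm$sequence, starts, ends)
  tibble::tibble(
    index = seq_len(k - 1),
    seq = seqs,
    length = as.integer(ends - starts),
    donor_dinucleotide = substr(seqs, 1, 2),
    acceptor_dinucleotide = substr(seqs, nchar(seqs) - 1, nchar(seqs))
  )
}

#' Extract a donor (5' splice site) junction sequence
#'
#' Returns the junction spanning the end of exon `intron_index` and the start
#' of intron `intron_index`: the last `exon_flank` exonic nucleotides followed
#' by the first `intron_flank` intronic nucleotides. Position labels run
#' `-exon_flank..-1` (exon) then `+1..+intron_flank` (intron), so the donor's
#' GT dinucleotide sits at `+1,+2` and the discriminant +6 site is the sixth
#' intronic base.
#'
#' @param gm a [gene_model()].
#' @param intron_index which intron's donor (1-based; intron i follows exon i).
#' @param exon_flank,intron_flank flank widths in nt (defaults 5 and 12).
#' @return a one-row tibble: `kind`, `intron_index`, `exon_flank`,
#'   `intron_flank`, `seq`, and a `positions` list-column of labels.
#' @export
extract_donor_site <- function(gm, intron_index, exon_flank = 5, intron_flank = 12) {
  introns <- derive_introns(gm)
  if (!intron_index %in% introns$index) {
    abort_spliceselect(sprintf("intron %d does not exist", intron_index),
                       "spliceselect_validation_error")
  }
  ex <- exon_seq(gm, intron_index)
  it <- introns$seq[introns$index == intron_index]
  if (exon_flank > nchar(ex) || intron_flank > nchar(it)) {
    abort_spliceselect(
      sprintf("flanks (%d, %d) exceed available lengths (exon %d nt, intron %d nt)",
              exon_flank, intron_flank, nchar(ex), nchar(it)),
      "spliceselect_truncated_site_error",
      available = c(exon = nchar(ex), intron = nchar(it))
    )
  }
  seq <- paste0(
    if (exon_flank > 0) substr(ex, nchar(ex) - exon_flank + 1, nchar(ex)) else "",
    if (intron_flank > 0) substr(it, 1, intron_flank) else ""
  )
  tibble::tibble(
    kind = "donor", intron_index = as.integer(intron_index),
    exon_flank = as.integer(exon_flank), intron_flank = as.integer(intron_flank),
    seq = seq,
    positions = list(c(if (exon_flank > 0) -(exon_flank:1) else integer(),
                       if (intron_flank > 0) seq_len(intron_flank) else integer()))
  )
}

#' Extract all donor junctions of a gene model
#'
#' @inheritParams extract_donor_site
#' @return tibble with one row per intron (columns as [extract_donor_site()]).
#' @export
extract_donor_sites <- function(gm, exon_flank = 5, intron_flank = 12) {
  introns <- derive_introns(gm)
  purrr::map_dfr(introns$index, extract_donor_site, gm = gm,
                 exon_flank = exon_flank, intron_flank = intron_flank)
}

#' Extract the 3' tail of an intron
#'
#' Used for branchpoint scanning near the acceptor site. If the intron is
#' shorter than `n` the whole intron is returned and flagged as truncated.
#'
#' @param gm a [gene_model()].
#' @param intron_index 1-based intron number.
#' @param n tail length in nt.
#' @return one-row tibble: `intron_index`, `n_requested`, `n_returned`,
#'   `truncated`, `seq`.
#' @export
extract_acceptor_tail <- function(gm, intron_index, n = 50) {
  introns <- derive_introns(gm)
  if (!intron_index %in% introns$index) {
    abort_spliceselect(sprintf("intron %d does not exist", intron_index),
                       "spliceselect_validation_error")
  }
  it <- introns$seq[introns$index == intron_index]
  m <- min(n, nchar(it))
  tibble::tibble(
    intron_index = as.integer(intron_index),
    n_requested = as.integer(n),
    n_returned = as.integer(m),
    truncated = m < n,
    seq = substr(it, nchar(it) - m + 1, nchar(it))
  )
}

#' Write extracted junctions as FASTA
#'
#' One record per junction, named `geneid|donor|intron_<i>`.
#'
#' @param junctions tibble from [extract_donor_sites()].
#' @param gene_id gene identifier used in record names.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(junctions, gene_id, path) {
  ss <- Biostrings::DNAStringSet(junctions$seq)
  names(ss) <- sprintf("%s|%s|intron_%d", gene_id, junctions$kind, junctions$intron_index)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Tabulate introns of one or more gene models
#'
#' @param gms a gene model or list of gene models.
#' @return tibble: `gene_id`, `intron_index`, `length`, `donor_dint`,
#'   `acceptor_dint`.
#' @export
intron_table <- function(gms) {
  if (inherits(gms, "gene_model")) gms <- list(gms)
  purrr::map_dfr(gms, function(gm) {
    it <- derive_introns(gm)
    tibble::tibble(gene_id = gm$gene_id, intron_index = it$index,
                   length = it$length, donor_dint = it$donor_dinucleotide,
                   acceptor_dint = it$acceptor_dinucleotide)
  })
}
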