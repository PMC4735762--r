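# End-to-end driver composing the analysis stages: gene models -> donor
# junctions -> PWM scoring -> branchpoint calls -> skipping prediction ->
# (optional) junction-read isoform evidence. Deterministic given the
# config and seed; every tabular output carries a config-hash provenance
# comment.

#' Validate a pipeline run configuration
#'
#' A config is a list (or YAML file path) with:
#' \describe{
#'   \item{genes}{a list of gene entries, each either `list(path=, format=,
#'     fasta=, species=, group=)` for annotated records, or
#'     `list(synthetic = list(...))` with [synth_gene_model()] arguments.}
#'   \item{pwm}{`"chr22"` (bundled donor PWM, default) or a TSV path from
#'     [write_pwm_tsv()].}
#'   \item{cassette_index}{cassette exon index (default 2).}
#'   \item{bps_window}{`c(lo, hi)` (default `c(20, 40)`).}
#'   \item{bps_tail_n}{scan window at each intron 3' end (default 50).}
#'   \item{rule}{`"plus6"` or `"pwms_delta"` (default `"plus6"`).}
#'   \item{delta_threshold}{for the `pwms_delta` rule (default 2).}
#'   \item{reads}{optional: per-gene `list(psi=, n=, read_len=, error_rate=)`
#'     to simulate, or a FASTA/FASTQ path; `flank` and `min_overhang`
#'     control the matcher.}
#'   \item{seed}{integer seed (default 1).}
#' }
#'
#' @param config list or YAML path.
#' @return the normalized config list (errors on invalid entries).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$genes) || !length(config$genes)) {
    abort_spliceselect("config has no gene entries", "spliceselect_config_error")
  }
  for (g in config$genes) {
    if (!is.null(g$path) && !file.exists(g$path)) {
      abort_spliceselect(sprintf("input path does not exist: %s", g$path),
                         "spliceselect_config_error")
    }
    if (is.null(g$path) && is.null(g$synthetic)) {
      abort_spliceselect("each gene entry needs `path` or `synthetic`",
                         "spliceselect_config_error")
    }
  }
  config$pwm <- config$pwm %||% "chr22"
  if (!identical(config$pwm, "chr22") && !file.exists(config$pwm)) {
    abort_spliceselect(sprintf("PWM file does not exist: %s", config$pwm),
                       "spliceselect_config_error")
  }
  config$cassette_index <- config$cassette_index %||% 2
  config$bps_window <- as.numeric(config$bps_window %||% c(20, 40))
  config$bps_tail_n <- config$bps_tail_n %||% 50
  config$rule <- config$rule %||% "plus6"
  config$delta_threshold <- config$delta_threshold %||% 2
  config$seed <- as.integer(config$seed %||% 1)
  if (length(config$bps_window) != 2 || config$bps_window[1] > config$bps_window[2]) {
    abort_spliceselect("bps_window must be c(lo, hi) with lo <= hi",
                       "spliceselect_config_error")
  }
  config
}

write_tsv_prov <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config-hash: %s  spliceselect %s", hash,
                     as.character(utils::packageVersion("spliceselect"))), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
}

#' Run the full splice-signal pipeline
#'
#' Executes extract -> PWM scoring -> branchpoint calls -> skipping
#' prediction (-> isoform evidence) over every configured gene and writes
#' `donors.tsv`, `bps_calls.tsv`, `skipping_calls.tsv`, optionally
#' `isoform_counts.tsv`, and `summary.json` into `out_dir`.
#'
#' @param config see [validate_run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the summary tibbles.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  hash <- rlang::hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pwm <- if (identical(config$pwm, "chr22")) chr22_donor_pwm() else read_pwm_tsv(config$pwm)
  ci <- config$cassette_index

  models <- purrr::imap(config$genes, function(g, i) {
    if (!is.null(g$synthetic)) {
      args <- g$synthetic
      args$seed <- args$seed %||% (config$seed + i)
      gm <- do.call(synth_gene_model, args)$gene_model
    } else {
      gm <- read_gene_model(g$path, format = g$format %||% "genbank",
                            fasta = g$fasta, transcript = g$transcript)
    }
    gm$species <- g$species %||% gm$species
    gm$group <- g$group %||% ""
    gm
  })

  donors <- purrr::map_dfr(models, function(gm) {
    d <- extract_donor_sites(gm, exon_flank = 5, intron_flank = 8)
    d$gene_id <- gm$gene_id
    d$species <- gm$species
    d$pwms <- score_sequences(pwm, d$seq)$score
    d$plus6 <- substr(d$seq, 5 + 6, 5 + 6)
    d[, c("gene_id", "species", "intron_index", "seq", "pwms", "plus6")]
  })

  bps <- purrr::map_dfr(models, function(gm) {
    it <- derive_introns(gm)
    out <- call_bps_panel(it, window = config$bps_window, tail_n = config$bps_tail_n)
    out$gene_id <- gm$gene_id
    out$species <- gm$species
    out
  })

  panel <- purrr::map_dfr(models, function(gm) {
    up <- donors[donors$gene_id == gm$gene_id & donors$intron_index == ci - 1, ]
    dn <- donors[donors$gene_id == gm$gene_id & donors$intron_index == ci, ]
    tibble::tibble(
      species = gm$species, group = gm$group, gene_id = gm$gene_id,
      exon_present = nrow(dn) > 0 && n_exons(gm) > ci,
      upstream_plus6 = up$plus6[1],
      downstream_plus6 = if (nrow(dn)) dn$plus6[1] else NA_character_,
      pwms6 = up$pwms[1],
      pwms7 = if (nrow(dn)) dn$pwms[1] else NA_real_
    )
  })
  calls <- classify_panel(panel, rule = config$rule,
                          delta_threshold = config$delta_threshold)

  counts <- NULL
  if (!is.null(config$reads)) {
    counts <- purrr::map_dfr(seq_along(models), function(i) {
      gm <- models[[i]]
      exons <- vapply(seq_len(n_exons(gm)), exon_seq, character(1), gm = gm)
      flank <- config$reads$flank %||% 20
      probes <- build_probes(exons[ci - 1], exons[ci], exons[ci + 1], flank = flank)
      if (!is.null(config$reads$path)) {
        rd <- config$reads$path
        lens <- NULL
      } else {
        sim <- synth_reads(gm, cassette_index = ci,
                           psi = config$reads$psi %||% 0.7,
                           n = config$reads$n %||% 2000,
                           read_len = config$reads$read_len %||% 80,
                           error_rate = config$reads$error_rate %||% 0,
                           seed = config$seed + 1000 + i)
        rd <- sim$reads$seq
        lens <- c(retained = sim$truth$retained_length,
                  skipped = sim$truth$skipped_length)
      }
      out <- count_support(rd, probes,
                           min_overhang = config$reads$min_overhang %||% 8,
                           transcript_lengths = lens)
      out$gene_id <- gm$gene_id
      out$species <- gm$species
      out
    })
  }

  write_tsv_prov(donors, file.path(out_dir, "donors.tsv"), hash)
  write_tsv_prov(bps, file.path(out_dir, "bps_calls.tsv"), hash)
  write_tsv_prov(calls, file.path(out_dir, "skipping_calls.tsv"), hash)
  if (!is.null(counts)) {
    write_tsv_prov(counts, file.path(out_dir, "isoform_counts.tsv"), hash)
  }
  summary <- list(
    config_hash = hash, seed = config$seed,
    species = purrr::map(seq_len(nrow(calls)), function(i) {
      row <- calls[i, ]
      gene_bps <- bps[bps$gene_id == row$gene_id, ]
      list(species = row$species, gene_id = row$gene_id,
           upstream_plus6 = row$upstream_plus6,
           downstream_plus6 = row$downstream_plus6,
           pwms6 = row$pwms6, pwms7 = row$pwms7,
           strong_bps = stats::setNames(as.list(gene_bps$strong_bps),
                                        paste0("intron_", gene_bps$intron_index)),
           call = row$call,
           isoform = if (!is.null(counts)) {
             as.list(counts[counts$gene_id == row$gene_id,
                            c("retained", "skipped", "psi", "ratio_long_short")])
           } else NULL)
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(donors = donors, bps = bps, calls = calls, counts = counts,
                 config_hash = hash))
}
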