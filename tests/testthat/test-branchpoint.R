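test_that("YURAY scanning finds all and only degenerate-motif offsets", {
  hits <- scan_yuray("AAACTAACAA")
  expect_equal(hits$start, 3L)
  expect_equal(hits$motif, "CTAAC")

  expect_equal(nrow(scan_yuray("AAAAAAAA")), 0)
  expect_equal(scan_yuray("CUAAC")$motif, "CTAAC")  # RNA input

  # overlapping hits are all reported
  over <- scan_yuray("CTAACTAAC")
  expect_equal(over$start, c(0L, 4L))

  agree <- withr::with_seed(42, {
    vapply(1:2000, function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), sample(5:80, 1), replace = TRUE),
                 collapse = "")
      identical(scan_yuray(s), brute_yuray(s))
    }, logical(1))
  })
  expect_true(all(agree))
})

test_that("no YURAY motif can contain an AG dinucleotide", {
  for (m in yuray_strings()) {
    expect_false(grepl("AG", m, fixed = TRUE))
  }
})

test_that("intervening-AG exclusion and 3'-distances follow the definition", {
  # 40-nt intron, CTAAC at 0-based 10, no other AG, terminal AG
  s <- paste0(strrep("C", 10), "CTAAC", strrep("C", 23), "AG")
  h <- classify_hits(s)
  expect_equal(nrow(h), 1)
  expect_equal(h$d_to3, 30)
  expect_true(h$is_candidate)

  # planting an AG at 0-based 25 disqualifies the motif
  s2 <- paste0(strrep("C", 10), "CTAAC", strrep("C", 10), "AG",
               strrep("C", 11), "AG")
  h2 <- classify_hits(s2)
  expect_true(h2$intervening_ag)
  expect_false(h2$is_candidate)

  # a motif occupying the final 5 nt has d_to3 = 5 (and triggers the
  # non-AG-terminus warning)
  s3 <- paste0(strrep("G", 20), "CTAAC")
  expect_warning(h3 <- classify_hits(s3), "does not end in AG")
  expect_equal(h3$d_to3[h3$start == 20], 5)

  agree <- withr::with_seed(7, {
    vapply(1:500, function(i) {
      s <- random_intron_ending_ag(sample(20:150, 1))
      got <- classify_hits(s)
      want <- brute_classify(s)
      identical(got$start, want$start) &&
        identical(as.integer(got$d_to3), as.integer(want$d_to3)) &&
        identical(got$intervening_ag, want$intervening_ag)
    }, logical(1))
  })
  expect_true(all(agree))
})

test_that("prefix extension leaves 3'-distances unchanged and shifts starts", {
  withr::with_seed(19, {
    s <- random_intron_ending_ag(80)
  })
  h <- classify_hits(s)
  for (k in c(1, 7, 30)) {
    ext <- paste0(strrep("C", k), s)
    h2 <- classify_hits(ext)
    shared <- h2[h2$start >= k, ]
    expect_equal(shared$start, h$start + k)
    expect_equal(shared$d_to3, h$d_to3)
  }
})

test_that("optimal-window estimation finds the smallest covering window", {
  w <- estimate_opt_window(rep(25, 12))
  expect_equal(c(w$lo, w$hi), c(25, 25))
  expect_equal(w$coverage, 1)

  w2 <- estimate_opt_window(c(20:29, 60, 200), coverage_target = 1.0)
  expect_equal(c(w2$lo, w2$hi), c(20, 200))

  # 80 values uniform on [20,40], 20 on [60,200], target 0.75
  d <- withr::with_seed(33, {
    c(sample(20:40, 80, replace = TRUE), sample(60:200, 20, replace = TRUE))
  })
  w3 <- estimate_opt_window(d, coverage_target = 0.75)
  expect_gte(w3$lo, 20)
  expect_lte(w3$hi, 40)
  expect_gte(w3$coverage, 0.75)

  # enumeration oracle: no window one narrower reaches the target
  width3 <- w3$hi - w3$lo
  if (width3 > 0) {
    narrower_cov <- vapply((min(d) - 1):max(d), function(lo) {
      mean(d >= lo & d <= lo + width3 - 1)
    }, numeric(1))
    expect_true(all(narrower_cov < 0.75))
  }

  expect_error(estimate_opt_window(1:5), class = "spliceselect_estimation_error")
})

test_that("strong-branchpoint calls respect the optimal window", {
  # clean CTAAC 35 nt from the 3' end -> strong
  s <- paste0(strrep("C", 40), "CTAAC", strrep("C", 28), "AG")
  res <- call_strong_bps(s, c(20, 40))
  expect_true(res$strong)
  expect_equal(res$best$d_to3, 35)
  expect_equal(res$best$motif, "CTAAC")

  # only YURAY at d = 85 -> not strong under [20, 40]
  s2 <- paste0(strrep("C", 20), "CTAAC", strrep("C", 78), "AG")
  expect_equal(nchar(s2) - 20, 85)
  res2 <- call_strong_bps(s2, c(20, 40))
  expect_false(res2$strong)

  # no YURAY at all
  res3 <- call_strong_bps(paste0(strrep("C", 50), "AG"), c(20, 40))
  expect_false(res3$strong)
  expect_null(res3$best)

  # equidistant candidates (d = 35 and 25 around midpoint 30): tie goes to
  # the smaller distance
  s4 <- paste0(strrep("C", 10), "CTAAC", strrep("C", 5), "CTAAC",
               strrep("C", 18), "AG")
  res4 <- call_strong_bps(s4, c(20, 40))
  expect_true(res4$strong)
  expect_equal(res4$best$d_to3, 25)
})

test_that("pipeline calls match brute force on random introns", {
  window <- c(20, 40)
  agree <- withr::with_seed(77, {
    vapply(1:1000, function(i) {
      s <- random_intron_ending_ag(sample(50:200, 1))
      call_strong_bps(s, window)$strong == brute_strong(s, window)
    }, logical(1))
  })
  expect_true(all(agree))
})

test_that("planted branchpoints are recovered with perfect sensitivity and specificity", {
  n_pos <- 0; n_neg <- 0; tp <- 0; tn <- 0
  for (seed in 1:25) {
    d <- 20 + (seed %% 21)
    g <- synth_gene_model(
      intron_lengths = c(400, 250),
      bps_plan = tibble::tibble(intron_index = 2, d_to3 = d),
      seed = seed
    )
    panel <- call_bps_panel(derive_introns(g$gene_model), window = c(20, 40))
    n_pos <- n_pos + 1
    n_neg <- n_neg + 1
    if (panel$strong_bps[2] && panel$best_d_to3[2] == d) tp <- tp + 1
    if (!panel$strong_bps[1]) tn <- tn + 1
  }
  expect_equal(tp / n_pos, 1.0)
  expect_equal(tn / n_neg, 1.0)
})

test_that("distance tables apply the short-intron filter", {
  introns <- c(
    paste0(strrep("C", 250), "CTAAC", strrep("C", 23), "AG"),  # long, d = 30
    paste0(strrep("C", 10), "CTAAC", strrep("C", 13), "AG")    # short (30 nt)
  )
  tab <- bps_distance_table(introns, min_intron_length = 200)
  expect_equal(unique(tab$intron), 1L)
  expect_equal(tab$d_to3, 30)
  tab_all <- bps_distance_table(introns, min_intron_length = 0)
  expect_equal(sort(unique(tab_all$intron)), c(1L, 2L))
  p <- plot_bps_distances(tab, window = c(20, 40))
  expect_s3_class(p, "ggplot")
})
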