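test_that("log-odds closed forms hold at pseudocount zero", {
  pwm <- build_pwm(rep("GT", 4), pseudocount = 0)
  expect_equal(pwm$scores["G", 1], log2(1 / 0.25))  # = 2
  expect_equal(pwm$scores["T", 2], 2)
  expect_equal(pwm$scores["A", 1], -30)  # floored, not -Inf
  expect_true(all(is.finite(pwm$scores)))

  # counts proportional to background -> all scores zero
  flat <- build_pwm(c("AA", "CC", "GG", "TT"), pseudocount = 0)
  expect_equal(unname(flat$scores), matrix(0, 4, 2))
})

test_that("pseudocounted frequencies are normalized and recover a planted matrix", {
  truth <- consensus_prob_matrix("CAGGTAAGT", p = 0.7)
  draws <- sample_donors(truth, 5000, seed = 11)
  pwm <- build_pwm(draws, position_labels = c(-3:-1, 1:6))
  expect_equal(unname(colSums(pwm$probs)), rep(1, 9), tolerance = 1e-12)

  emp <- sweep(pwm$counts, 2, pwm$n, "/")
  expect_lt(max(abs(emp - truth)), 0.02)

  # monotone recovery with growing n (fixed seed per size)
  errs <- vapply(c(50, 500, 5000), function(n) {
    d <- sample_donors(truth, n, seed = 101)
    p <- build_pwm(d)
    max(abs(sweep(p$counts, 2, p$n, "/") - truth))
  }, numeric(1))
  expect_true(errs[3] <= errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("ragged junction sets and degenerate backgrounds are rejected", {
  expect_error(build_pwm(c("GT", "GTA")), class = "spliceselect_shape_error")
  expect_error(build_pwm(c("GT", "GT"), background = c(A = 1, C = 0, G = 0, T = 0)),
               class = "spliceselect_background_error")
  expect_error(score_sequence(chr22_donor_pwm(), "GT"),
               class = "spliceselect_shape_error")
})

test_that("PWMS is additive and column-monotone", {
  pwm <- chr22_donor_pwm()
  seqs <- c("TCAAAGTAAGTGA", "AGGGGGTAAGAGC", "GCAAAGTAAGAGT")
  for (s in seqs) {
    res <- score_sequence(pwm, s)
    expect_equal(res$score, sum(res$per_position_contributions[[1]]))
    expect_equal(res$score, naive_pwms(pwm$scores, s))
  }
  # ambiguity symbols contribute zero
  expect_equal(score_sequence(pwm, "NCAAAGTAAGTGA")$score,
               score_sequence(pwm, "TCAAAGTAAGTGA")$score -
                 pwm$scores["T", 1])

  # exhaustive single-base substitutions: moving to a lower-valued column
  # entry strictly decreases the score
  cons <- as.character(pwm_consensus(pwm))
  base_score <- score_sequence(pwm, cons)$score
  for (j in seq_len(nchar(cons))) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(cons, j, j)) next
      mut <- cons
      substr(mut, j, j) <- b
      expect_lt(score_sequence(pwm, mut)$score, base_score)
    }
  }
})

test_that("consensus of the chromosome-22 donor matrix is CAG|GTAAGT over -3..+6", {
  pwm <- chr22_donor_pwm()
  cons <- pwm_consensus(pwm)
  expect_false(any(attr(cons, "ties")))
  core <- substr(as.character(cons), 3, 11)  # positions -3..-1, +1..+6
  expect_equal(core, "CAGGTAAGT")
})

test_that("uniform matrices flag consensus ties and planted consensus is recovered", {
  flat <- build_pwm(c("AA", "CC", "GG", "TT"), pseudocount = 0)
  expect_true(all(attr(pwm_consensus(flat), "ties")))

  truth <- consensus_prob_matrix("CAGGTAAGT", p = 0.7)
  pwm <- build_pwm(sample_donors(truth, 2000, seed = 5))
  expect_equal(as.character(pwm_consensus(pwm)), "CAGGTAAGT")
})

test_that("max_score is the column-max sum and bounds random sequences", {
  pwm <- chr22_donor_pwm()
  expect_equal(max_score(pwm), 14.3656, tolerance = 1e-9)
  expect_equal(score_sequence(pwm, as.character(pwm_consensus(pwm)))$score,
               max_score(pwm))

  zero <- pwm
  zero$scores[] <- 0
  expect_equal(max_score(zero), 0)

  rand <- withr::with_seed(21, vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 13, replace = TRUE), collapse = "")
  }, character(1)))
  expect_true(all(score_sequences(pwm, rand)$score <= max_score(pwm)))
})

test_that("column information matches the entropy formula", {
  fixed <- build_pwm(rep("G", 3) |> paste0("T"), pseudocount = 0)
  info <- column_information(fixed)
  expect_equal(info$information, c(2, 2))

  flat <- build_pwm(c("AA", "CC", "GG", "TT"), pseudocount = 0)
  expect_equal(column_information(flat)$information, c(0, 0))

  truth <- consensus_prob_matrix("GTAAGT", p = 0.6)
  pwm <- build_pwm(sample_donors(truth, 500, seed = 3), pseudocount = 0.5)
  info <- column_information(pwm)
  # independent evaluation from the probability matrix
  expected <- apply(pwm$probs, 2, function(p) {
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  })
  expect_equal(info$information, unname(expected))
})

test_that("paired site-strength comparison matches the textbook t formula", {
  same <- paired_pwms_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  shifted <- paired_pwms_test(c(1, 1, 1, 1), c(0, 0, 0, 0))
  expect_equal(shifted$mean_diff, 1)
  expect_true(shifted$degenerate)
  expect_equal(shifted$t_statistic, Inf)

  withr::with_seed(13, {
    a <- rnorm(12, mean = 9, sd = 1)
    b <- a - rnorm(12, mean = 2, sd = 0.5)
  })
  res <- paired_pwms_test(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(12))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 11)
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-9)
  expect_equal(res$degrees_of_freedom, 11L)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  expect_false(res$degenerate)
})

test_that("PWM TSV round-trip preserves scores and metadata", {
  truth <- consensus_prob_matrix("GTAAGT", p = 0.8)
  pwm <- build_pwm(sample_donors(truth, 200, seed = 8),
                   position_labels = 1:6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_tsv(pwm, path)
  back <- read_pwm_tsv(path)
  expect_equal(back$scores, pwm$scores, tolerance = 1e-12)
  expect_equal(back$n, pwm$n)
  expect_equal(back$pseudocount, pwm$pseudocount)
  expect_equal(score_sequence(back, "GTAAGT")$score,
               score_sequence(pwm, "GTAAGT")$score, tolerance = 1e-12)
})

test_that("tidy, glance and autoplot summarise a PWM", {
  pwm <- build_pwm(sample_donors(consensus_prob_matrix("GTAAGT"), 100, seed = 2))
  td <- generics::tidy(pwm)
  expect_equal(nrow(td), 4 * 6)
  expect_true(all(c("position", "base", "score", "count", "freq") %in% names(td)))
  gl <- generics::glance(pwm)
  expect_equal(gl$n, 100)
  expect_equal(gl$consensus, as.character(pwm_consensus(pwm)))
  p <- ggplot2::autoplot(pwm)
  expect_s3_class(p, "ggplot")
})
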