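test_that("SLS scoring reproduces hand-computed totals", {
  s <- score_sls(c(8, 9, 10, 11, 12), c(8, 9, 10, 11, 12), delay_correct = 24)
  expect_equal(s$trials_1_5_total, 50L)
  expect_equal(s$sum_of_trials, 74L)
  expect_equal(s$max_learning_span, 12L)

  s0 <- score_sls(c(8, 9, 10, 11, 12), c(0, 0, 0, 0, 0), delay_correct = 0)
  expect_equal(s0$sum_of_trials, 0L)

  s2 <- score_sls(c(8, 8, 8, 8, 8), c(4, 4, 4, 4, 4), delay_correct = 5)
  expect_equal(s2$sum_of_trials, 25L)
  expect_equal(s2$max_learning_span, 8L)
})

test_that("SLS validation names the violated constraint", {
  expect_error(score_sls(c(8, 9, 10, 11, 24), rep(0, 5), 0), "\\[2, 23\\]")
  expect_error(score_sls(c(7, 8, 8, 8, 8), rep(0, 5), 0), "trial_spans")
  expect_error(score_sls(c(8, 8, 8, 8, 8), c(9, 0, 0, 0, 0), 0), "trial_correct")
  expect_error(score_sls(c(8, 8, 8, 8, 8), c(0, 0, 0, 0, -1), 0), "trial_correct")
  expect_error(score_sls(c(8, 8, 8, 8, 8), rep(0, 5), -1), "delay_correct")
  expect_error(score_sls(c(8, 8, 8, 8, 8), rep(8, 5), 9, delay_presented = 8),
               "delay_correct")
  expect_error(score_sls(c(8, 9, 8, 8, 8), rep(0, 5), 0, delay_presented = 8),
               "delay_presented")
})

test_that("accuracy weighting matches the step table at every boundary", {
  expect_equal(accuracy_weight(34), 1)
  expect_equal(accuracy_weight(35), 2)
  expect_equal(accuracy_weight(41), 2)
  expect_equal(accuracy_weight(42), 3)
  expect_equal(accuracy_weight(43), 4)
  expect_equal(accuracy_weight(47), 5)
  expect_equal(accuracy_weight(c(48, 44, 20)), c(5, 4.25, 1))
  expect_error(accuracy_weight(49), "\\[0, 48\\]")
  expect_error(accuracy_weight(-1), "\\[0, 48\\]")
})

test_that("Symbols scoring evaluates SYM and SYMaw per definition", {
  s <- score_symbols(rep(TRUE, 48), rep(3, 48))
  expect_equal(s$sym, 3)
  expect_equal(s$accuracy_weight, 5)
  expect_equal(s$symaw, 35)

  # 40 correct at 4 s, 8 incorrect at arbitrary rt
  s2 <- score_symbols(c(rep(TRUE, 40), rep(FALSE, 8)),
                      c(rep(4, 40), rep(9, 8)))
  expect_equal(s2$sym, 4)
  expect_equal(s2$accuracy_weight, 2)
  expect_equal(s2$symaw, 12)

  # SYM at or above 10 s floors SYMaw at 0 regardless of accuracy
  s3 <- symbols_scores_from_summary(sym = c(10, 12), n_correct = c(48, 48))
  expect_equal(s3$symaw, c(0, 0))

  expect_error(score_symbols(rep(TRUE, 48), c(rep(3, 47), -1)), "positive")
  expect_error(score_symbols(rep(TRUE, 47), rep(3, 47)), "48")
})

test_that("sessions with zero correct Symbols items give missing SYM, not zero", {
  expect_warning(s <- score_symbols(rep(FALSE, 48), rep(3, 48)), "zero correct")
  expect_true(is.na(s$sym))
  expect_true(is.na(s$symaw))
  expect_equal(s$n_correct, 0L)
})

test_that("SYMaw is monotone: non-increasing in SYM, non-decreasing in accuracy", {
  syms <- seq(0.5, 12, by = 0.25)
  for (nc in c(20, 35, 42, 44, 48)) {
    v <- symbols_scores_from_summary(syms, rep(nc, length(syms)))$symaw
    expect_true(all(diff(v) <= 0))
  }
  for (sym in c(2, 5, 9.5)) {
    v <- symbols_scores_from_summary(rep(sym, 49), 0:48)$symaw
    expect_true(all(diff(v) >= 0))
  }
})

test_that("raw composite adds Sum of Trials and SYMaw with missing propagation", {
  expect_equal(compute_mtd_sbcr(74, 35), 109)
  expect_equal(compute_mtd_sbcr(0, 0), 0)
  expect_equal(compute_mtd_sbcr(25, 12), 37)
  expect_true(is.na(compute_mtd_sbcr(NA, 12)))
  expect_true(is.na(compute_mtd_sbcr(25, NA)))
})

test_that("reference statistics use only the masked subgroup with n-1 SD", {
  r <- reference_stats(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(r$mean, 2)
  expect_equal(r$sd, 1)
  r2 <- reference_stats(c(1, 2, 3, 100), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r2$mean, 2)
  expect_equal(r2$sd, 1)
  expect_equal(r2$n, 3L)
  expect_error(reference_stats(c(5, 5, 5), rep(TRUE, 3), "flat"), "zero variance.*flat")
  expect_error(reference_stats(c(1, NA, NA), rep(TRUE, 3)), "fewer than 2")
})

test_that("z-composite averages signed reference z-scores", {
  refs <- list(a = list(mean = 0, sd = 1), b = list(mean = 0, sd = 1))
  # participant at the reference means scores zero
  expect_equal(
    z_composite(data.frame(a = 0, b = 0), refs, c(a = 1, b = 1),
                restandardize = FALSE), 0)
  # symmetric +1 / -1 constituents cancel
  expect_equal(
    z_composite(data.frame(a = 1, b = -1), refs, c(a = 1, b = 1),
                restandardize = FALSE), 0)
  # sign flip turns a raw z of -0.5 into +0.5
  refs4 <- list(a = list(mean = 0, sd = 1), b = list(mean = 0, sd = 1),
                c = list(mean = 0, sd = 1), d = list(mean = 0, sd = 1))
  got <- z_composite(data.frame(a = 0.5, b = 0.5, c = 0.5, d = -0.5),
                     refs4, c(a = 1, b = 1, c = 1, d = -1),
                     restandardize = FALSE)
  expect_equal(got, 0.5)
  # missing constituent gives missing composite
  got2 <- z_composite(data.frame(a = c(1, NA), b = c(1, 1)), refs,
                      c(a = 1, b = 1), restandardize = FALSE)
  expect_true(is.na(got2[2]) && !is.na(got2[1]))
})

test_that("sum_of_trials identity holds on every scored synthetic session", {
  sc <- cached_scored(2000, 42)
  expect_equal(sc$sls_sum_of_trials, sc$sls_t15_total + sc$sls_delay)
})

test_that("constituent z-transforms normalize the reference subgroup", {
  sc <- cached_scored(2000, 42)
  cu <- sc$diagnosis == "CU"
  for (v in c("sls_max_span", "sls_t15_total", "sls_delay", "sym")) {
    ref <- reference_stats(sc[[v]], cu, v)
    z <- z_score(sc[[v]], ref)
    expect_lt(abs(mean(z[cu & !is.na(z)])), 1e-12)
    expect_lt(abs(sd(z[cu & !is.na(z)]) - 1), 1e-12)
  }
})

test_that("summary-path and session-path scoring agree exactly", {
  co <- cached_cohort(500, 9)
  sc <- score_cohort(co)
  summary_df <- data.frame(
    id = co$participants$id,
    diagnosis = co$participants$diagnosis,
    sls_t15_total = sc$sls_t15_total,
    sls_delay = sc$sls_delay,
    sls_max_span = sc$sls_max_span,
    sym = sc$sym,
    sym_n_correct = sc$sym_n_correct
  )
  sc2 <- score_summary(summary_df)
  for (v in c("symaw", "mtd_sbcr", "mtd_sbcz", "sls_sum_of_trials")) {
    expect_equal(sc2[[v]], sc[[v]], tolerance = 1e-12)
  }
})
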