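test_that("Hedge's g matches hand computation and the raw path equals the summary path", {
  g <- hedges_g(c(1, 2, 3), c(2, 3, 4))
  # pooled SD 1, J = 1 - 3/15 = 0.8, so g = 0.8
  expect_equal(g$g, 0.8)
  expect_lt(g$ci_low, 0.8)
  expect_gt(g$ci_high, 0.8)

  g0 <- hedges_g_from_summary(5, 2, 20, 5, 3, 25)
  expect_equal(g0$g, 0)
  expect_equal(g0$ci_low, -g0$ci_high)

  set.seed(11)
  for (i in 1:20) {
    x1 <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    x2 <- rnorm(sample(5:40, 1), 1, sd = runif(1, 0.5, 3))
    raw <- hedges_g(x1, x2)
    summ <- hedges_g_from_summary(mean(x1), sd(x1), length(x1),
                                  mean(x2), sd(x2), length(x2))
    expect_equal(raw$g, summ$g, tolerance = 1e-12)
    expect_equal(raw$ci_low, summ$ci_low, tolerance = 1e-12)
    expect_equal(raw$ci_high, summ$ci_high, tolerance = 1e-12)
  }
  expect_error(hedges_g(c(1, 1, 1), c(1, 1)), "pooled SD")
  expect_error(hedges_g_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("the CI formula reproduces the published effect-size column from summaries", {
  tab <- mcsa_group_summaries
  # the z-composite row (mtd_sbcz) is a study-internal re-standardization
  # whose printed g is not a function of the printed summaries; all other
  # cognitive and imaging g's must reproduce to +/- 0.03
  rows <- tab[tab$domain %in% c("cognition_remote", "cognition_in_person",
                                "imaging") & tab$variable != "mtd_sbcz", ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    g <- hedges_g_from_summary(r$cu_mean, r$cu_sd, r$cu_n,
                               r$imp_mean, r$imp_sd, r$imp_n)
    expect_lt(abs(g$g - r$pub_g), 0.03)
  }
  # CI bounds additionally reproduce for the rows with near-complete
  # data; the in-person measures with missingness concentrated in the
  # impaired subgroup (Mayo-PACC, Global-z, Trails B, Digit Symbol)
  # have printed CIs computed on smaller undisclosed group n's
  ci_rows <- rows[!rows$variable %in%
                    c("mayo_pacc", "global_z", "trails_b", "digit_symbol"), ]
  for (i in seq_len(nrow(ci_rows))) {
    r <- ci_rows[i, ]
    g <- hedges_g_from_summary(r$cu_mean, r$cu_sd, r$cu_n,
                               r$imp_mean, r$imp_sd, r$imp_n)
    expect_lt(abs(g$ci_low - r$pub_ci_low), 0.03)
    expect_lt(abs(g$ci_high - r$pub_ci_high), 0.03)
  }
})

test_that("Spearman rho matches its definition and is rank-invariant", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  x <- c(0.3, 1.8, -0.4, 2.2, 0.9)
  expect_equal(spearman(x, exp(x))$rho, 1)   # monotone transform invariance
  expect_warning(r <- spearman(c(1, 1, 1, 1), 1:4), "constant")
  expect_true(is.na(r$rho))
  expect_error(spearman(1:2, 1:2), "fewer than 3")
})

test_that("Spearman equals brute-force rank-Pearson on a small-n random battery", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman(x, y)$rho, brute_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("grouped Spearman computes within each diagnostic category", {
  set.seed(14)
  g <- rep(c("CU", "MCI"), each = 30)
  x <- rnorm(60)
  y <- x + rnorm(60, 0, ifelse(g == "CU", 3, 0.3))
  tab <- spearman_by_group(x, y, g)
  expect_setequal(tab$group, c("CU", "MCI"))
  expect_gt(tab$rho[tab$group == "MCI"], tab$rho[tab$group == "CU"])
  expect_equal(tab$rho[tab$group == "CU"],
               spearman(x[g == "CU"], y[g == "CU"])$rho)
})

test_that("Fisher's exact p matches exhaustive hypergeometric enumeration", {
  set.seed(15)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- group_compare(tab, kind = "fisher")$p
    expect_equal(got, brute_fisher(tab), tolerance = 1e-10)
  }
  got <- group_compare(matrix(c(1, 11, 9, 3), 2, 2), kind = "fisher")$p
  expect_equal(got, brute_fisher(matrix(c(1, 11, 9, 3), 2, 2)), tolerance = 1e-10)
})

test_that("chi-square and t tests behave at their symmetry points", {
  r <- group_compare(matrix(c(10, 10, 10, 10), 2, 2), kind = "chisq")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 1)
  r2 <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3), kind = "t")
  expect_equal(unname(r2$statistic), 0)
  expect_error(group_compare(1:5, rep("a", 5), kind = "t"), "two non-empty groups")
})

test_that("adjusted association recovers an identity regression", {
  set.seed(16)
  n <- 200
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 1e-8)
  r <- fit_adjusted_association(y, x, age = rnorm(n, 70, 10),
                                sex = sample(c("F", "M"), n, TRUE),
                                education = rnorm(n, 16, 2),
                                reference_mask = rep(TRUE, n))
  expect_equal(r$estimate, 1, tolerance = 1e-6)
  expect_lt(r$p, 1e-10)
})

test_that("adjusted association is invariant to affine rescaling of raw scales", {
  set.seed(17)
  n <- 400
  age <- rnorm(n, 70, 10)
  x <- rnorm(n) + 0.02 * age
  y <- -0.3 * x + rnorm(n) - 0.03 * age
  sex <- sample(c("F", "M"), n, TRUE)
  edu <- rnorm(n, 16, 2)
  ref <- rep(TRUE, n)
  a <- fit_adjusted_association(y, x, age, sex, edu, ref)
  b <- fit_adjusted_association(100 + 7 * y, -2 * x + 3, age, sex, edu, ref)
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("a null predictor yields a near-zero standardized estimate", {
  set.seed(18)
  n <- 5000
  age <- rnorm(n, 70, 10)
  y <- rnorm(n) - 0.05 * age
  x <- rnorm(n)
  r <- fit_adjusted_association(y, x, age, sample(c("F", "M"), n, TRUE),
                                rnorm(n, 16, 2), rep(TRUE, n))
  expect_lt(abs(r$estimate), 0.05)
  expect_error(
    fit_adjusted_association(y, rep(1, n), age, rep("F", n), rnorm(n),
                             rep(TRUE, n)), "zero variance")
})

test_that("adjusted group differences respect confounding structure", {
  set.seed(19)
  n <- 3000
  age <- rnorm(n, 70, 8)
  sex <- sample(c("F", "M"), n, TRUE)
  edu <- rnorm(n, 16, 2)
  # fully mediated difference: score depends only on age, groups split by age
  score <- 2 * age + rnorm(n)
  group <- ifelse(age > 70, "impaired", "unimpaired")
  adj <- adjusted_group_difference(score, group, age, sex, edu)
  expect_lt(abs(adj$estimate), 0.2)
  # no confounding: random groups, injected shift; adjusted ~ unadjusted
  group2 <- sample(c("A", "B"), n, TRUE)
  score2 <- rnorm(n) + 1.5 * (group2 == "B")
  adj2 <- adjusted_group_difference(score2, group2, age, sex, edu)
  unadj <- mean(score2[group2 == "B"]) - mean(score2[group2 == "A"])
  expect_lt(abs(adj2$estimate - unadj), 0.1)
  expect_error(adjusted_group_difference(score2, rep("A", n), age, sex, edu),
               "two groups")
})
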