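#' Covariate-adjusted standardized association
#'
#' Ordinary least squares of the z-scored outcome on the z-scored
#' predictor plus age, sex and education, the primary analysis model
#' for biomarker-cognition associations. Outcome and predictor are both
#' z-scored against the reference subgroup before fitting, so the
#' reported coefficient is a standardized mean estimate comparable
#' across outcomes and predictors. Complete cases only; the 95% CI uses
#' the t distribution on the residual degrees of freedom.
#'
#' @param outcome,predictor numeric vectors (raw scale; standardization
#'   is internal).
#' @param age,education numeric covariate vectors.
#' @param sex character/factor covariate ("F"/"M" or any two levels).
#' @param reference_mask logical vector designating the z-score
#'   reference subgroup.
#' @return data frame (one row) with `estimate`, `ci_low`, `ci_high`,
#'   `p`, `n`.
#' @export
fit_adjusted_association <- function(outcome, predictor, age, sex, education,
                                     reference_mask) {
  sex_ind <- as.numeric(factor(sex)) - 1
  ok <- stats::complete.cases(outcome, predictor, age, sex_ind, education)
  if (sum(ok) < 10) {
    stop("fit_adjusted_association: fewer than 10 complete cases")
  }
  if (stats::sd(predictor[ok]) == 0) {
    stop("fit_adjusted_association: predictor has zero variance")
  }
  zy <- z_score(outcome, reference_stats(outcome, reference_mask, "outcome"))
  zx <- z_score(predictor, reference_stats(predictor, reference_mask, "predictor"))
  dat <- data.frame(zy = zy[ok], zx = zx[ok], age = age[ok],
                    sex = sex_ind[ok], education = education[ok])
  fit <- stats::lm(zy ~ zx + age + sex + education, data = dat)
  if (fit$rank < 5 && stats::sd(dat$sex) > 0) {
    stop("fit_adjusted_association: rank-deficient design")
  }
  .extract_coef(fit, "zx", nrow(dat))
}

#' Covariate-adjusted between-group difference
#'
#' OLS of a score on a two-level diagnostic-group indicator plus age,
#' sex and education; returns the group coefficient (second level minus
#' first) with its CI and p-value.
#'
#' @param score numeric outcome vector.
#' @param group two-level factor/character vector.
#' @param age,sex,education covariates as in
#'   [fit_adjusted_association()].
#' @return data frame (one row) with `estimate`, `ci_low`, `ci_high`,
#'   `p`, `n`.
#' @export
adjusted_group_difference <- function(score, group, age, sex, education) {
  group <- factor(group)
  sex_ind <- as.numeric(factor(sex)) - 1
  ok <- stats::complete.cases(score, group, age, sex_ind, education)
  if (length(unique(group[ok])) != 2) {
    stop("adjusted_group_difference: exactly two groups required")
  }
  g <- as.numeric(group[ok] == levels(droplevels(group[ok]))[2])
  dat <- data.frame(y = score[ok], g = g, age = age[ok],
                    sex = sex_ind[ok], education = education[ok])
  fit <- stats::lm(y ~ g + age + sex + education, data = dat)
  .extract_coef(fit, "g", nrow(dat))
}

.extract_coef <- function(fit, term, n) {
  sm <- summary(fit)$coefficients
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  df <- fit$df.residual
  tcrit <- stats::qt(0.975, df)
  data.frame(estimate = est, ci_low = est - tcrit * se,
             ci_high = est + tcrit * se,
             p = sm[term, "Pr(>|t|)"], n = n)
}

#' Hedge's g from raw data
#'
#' Bias-corrected standardized mean difference between two groups,
#' reported as group 2 minus group 1 over the pooled SD, with the
#' small-sample correction `J = 1 - 3 / (4 df - 1)` (df = n1 + n2 - 2)
#' and a normal-approximation 95% CI
#' `g +/- 1.96 * sqrt((n1 + n2) / (n1 n2) + g^2 / (2 df))`.
#'
#' @param group1_values,group2_values numeric vectors (`NA` dropped).
#' @return data frame (one row) with `g`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4))
hedges_g <- function(group1_values, group2_values) {
  x1 <- group1_values[!is.na(group1_values)]
  x2 <- group2_values[!is.na(group2_values)]
  hedges_g_from_summary(mean(x1), stats::sd(x1), length(x1),
                        mean(x2), stats::sd(x2), length(x2))
}

#' Hedge's g from summary statistics
#'
#' Same estimator as [hedges_g()] computed from published group means,
#' SDs and sizes, so that printed summary tables can be fed through the
#' identical code path (the two paths agree exactly on equivalent
#' input).
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return data frame (one row) with `g`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
#' @examples
#' hedges_g_from_summary(107.653, 20.171, 643, 66.314, 25.200, 41)
hedges_g_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("hedges_g: both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("hedges_g: SDs must be non-negative")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  if (sp == 0) stop("hedges_g: pooled SD is zero")
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (m2 - m1) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))
  data.frame(g = g, ci_low = g - 1.96 * se, ci_high = g + 1.96 * se,
             n1 = n1, n2 = n2)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of average (mid) ranks; the two-sided
#' p-value uses the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))`
#' on n - 2 degrees of freedom. Pairs with any missing value are
#' dropped; constant vectors give missing rho with a warning.
#'
#' @param x,y numeric vectors.
#' @return data frame (one row) with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearman: constant vector; rho undefined")
    return(data.frame(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  data.frame(rho = rho, p = p, n = n)
}

#' Spearman correlations within diagnostic groups
#'
#' @param x,y numeric vectors.
#' @param group factor/character grouping vector (e.g. diagnosis).
#' @return data frame with one row per group: `group`, `rho`, `p`, `n`.
#' @export
spearman_by_group <- function(x, y, group) {
  groups <- unique(as.character(group[!is.na(group)]))
  out <- lapply(groups, function(g) {
    sel <- !is.na(group) & group == g
    res <- spearman(x[sel], y[sel])
    cbind(data.frame(group = g), res)
  })
  do.call(rbind, out)
}

#' Unadjusted two-group comparison
#'
#' Between-group tests used for descriptive characteristics tables:
#' pooled-variance two-sample t-test for continuous variables
#' (`kind = "t"`; Welch via `var_equal = FALSE`), Pearson chi-square
#' without continuity correction (`kind = "chisq"`) or Fisher's exact
#' test (`kind = "fisher"`) for a 2 x k (chi-square) or 2 x 2 (Fisher)
#' count table.
#'
#' @param values numeric vector (for `kind = "t"`) or a count matrix
#'   (for `"chisq"` / `"fisher"`).
#' @param groups two-level grouping vector (for `kind = "t"`).
#' @param kind one of "t", "chisq", "fisher".
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return data frame (one row) with `test`, `statistic` (`NA` for
#'   Fisher), `p`.
#' @export
group_compare <- function(values, groups = NULL,
                          kind = c("t", "chisq", "fisher"),
                          var_equal = TRUE) {
  kind <- match.arg(kind)
  if (kind == "t") {
    groups <- factor(groups)
    if (nlevels(droplevels(groups[!is.na(values)])) != 2) {
      stop("group_compare: t-test needs exactly two non-empty groups")
    }
    tt <- stats::t.test(values ~ groups, var.equal = var_equal)
    return(data.frame(test = "t", statistic = unname(tt$statistic),
                      p = tt$p.value))
  }
  counts <- as.matrix(values)
  if (any(counts < 0)) stop("group_compare: counts must be non-negative")
  if (kind == "chisq") {
    ct <- stats::chisq.test(counts, correct = FALSE)
    return(data.frame(test = "chisq", statistic = unname(ct$statistic),
                      p = ct$p.value))
  }
  if (!all(dim(counts) == c(2, 2))) {
    stop("group_compare: fisher needs a 2x2 count table")
  }
  ft <- stats::fisher.test(counts)
  data.frame(test = "fisher", statistic = NA_real_, p = ft$p.value)
}
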