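#' Simulate Stricker Learning Span sessions
#'
#' Item-level simulation of the computer-adaptive list-learning test.
#' Trial 1 presents 8 words; after each trial the span adapts (all items
#' correct: +4; at least 75% correct: +1; more than 50%: unchanged;
#' otherwise -2), clamped to 2-23 words, so a perfect performer reaches
#' the 23-word ceiling by trial 5. Each presented word is recognized
#' correctly with probability `0.25 + 0.75 * plogis(theta - d(pos))`:
#' the 0.25 floor is forced guessing on the four-choice recognition
#' format, and item difficulty `d(pos)` increases mildly with serial
#' position. The delay trial presents every unique word seen on trials
#' 1-5 (word lists are nested, so this equals the maximum span) with a
#' fixed extra difficulty offset.
#'
#' @param latent_memory numeric vector of latent memory abilities (one
#'   session is simulated per element); `+Inf`/`-Inf` give
#'   ceiling/guessing-floor behavior.
#' @param params SLS parameter list (see [cohort_config()]).
#' @return list with matrices `spans`, `correct` (n x 5) and vectors
#'   `delay_presented`, `delay_correct`.
#' @export
simulate_sls_sessions <- function(latent_memory, params = cohort_config()$sls) {
  n <- length(latent_memory)
  pos_diff <- params$diff_base + params$diff_slope * (0:22)
  # per-item success probabilities (n x 23); constant across trials
  pm <- 0.25 + 0.75 * stats::plogis(outer(latent_memory, pos_diff, `-`))
  spans <- matrix(0L, n, 5)
  correct <- matrix(0L, n, 5)
  span <- rep(8L, n)
  pos_idx <- matrix(rep(1:23, each = n), n, 23)
  for (t in 1:5) {
    spans[, t] <- span
    hits <- matrix(stats::runif(n * 23), n, 23) < pm
    ct <- as.integer(rowSums(hits & (pos_idx <= span)))
    correct[, t] <- ct
    acc <- ct / span
    delta <- ifelse(acc == 1, params$step_up_all,
             ifelse(acc >= params$acc_up, params$step_up_most,
             ifelse(acc > params$acc_down, 0L, -params$step_down)))
    span <- pmin(23L, pmax(2L, span + as.integer(delta)))
  }
  presented <- do.call(pmax, as.data.frame(spans))
  pmd <- 0.25 + 0.75 * stats::plogis(
    outer(latent_memory, pos_diff + params$delay_offset, `-`))
  dhits <- matrix(stats::runif(n * 23), n, 23) < pmd
  delay_correct <- as.integer(rowSums(dhits & (pos_idx <= presented)))
  list(spans = spans, correct = correct,
       delay_presented = as.integer(presented),
       delay_correct = delay_correct)
}

#' Simulate a single SLS session
#'
#' Scalar convenience wrapper around [simulate_sls_sessions()].
#'
#' @inheritParams simulate_sls_sessions
#' @return list with `trial_spans`, `trial_correct`, `delay_presented`,
#'   `delay_correct`.
#' @export
simulate_sls_session <- function(latent_memory, params = cohort_config()$sls) {
  stopifnot(length(latent_memory) == 1)
  s <- simulate_sls_sessions(latent_memory, params)
  list(trial_spans = as.integer(s$spans[1, ]),
       trial_correct = as.integer(s$correct[1, ]),
       delay_presented = s$delay_presented[1],
       delay_correct = s$delay_correct[1])
}

#' Simulate Symbols Test sessions
#'
#' 48 symbol-matching items per session. Response times are log-normal
#' with location decreasing in latent speed; per-item accuracy is
#' Bernoulli with a high baseline (most participants at or near the
#' 48/48 ceiling, matching the strongly skewed accuracy distribution of
#' the real test) that degrades for low latent speed.
#'
#' @param latent_speed numeric vector of latent processing-speed
#'   abilities.
#' @param params Symbols parameter list (see [cohort_config()]);
#'   `rt_sigma = 0` gives deterministic response times equal to the
#'   location parameter.
#' @return list with n x 48 matrices `correct` (logical) and `rt` (seconds).
#' @export
simulate_symbols_sessions <- function(latent_speed, params = cohort_config()$symbols) {
  n <- length(latent_speed)
  p_acc <- stats::plogis(params$acc_int + params$acc_beta * latent_speed)
  correct <- matrix(stats::runif(n * 48), n, 48) < p_acc
  loc <- params$rt_mu - params$rt_beta * latent_speed
  rt <- exp(loc + params$rt_sigma * matrix(stats::rnorm(n * 48), n, 48))
  list(correct = correct, rt = rt)
}

#' Simulate a single Symbols session
#'
#' @inheritParams simulate_symbols_sessions
#' @return list with length-48 vectors `correct` and `rt_seconds`.
#' @export
simulate_symbols_session <- function(latent_speed, params = cohort_config()$symbols) {
  stopifnot(length(latent_speed) == 1)
  s <- simulate_symbols_sessions(latent_speed, params)
  list(correct = s$correct[1, ], rt_seconds = s$rt[1, ])
}

#' Simulate imaging biomarkers
#'
#' Generates amyloid, tau meta-ROI and tau entorhinal-ROI SUVRs
#' (log-normal with per-diagnosis location/scale matched by moment
#' inversion to the configured natural-scale means/SDs, plus an age
#' loading), hippocampal and intracranial volumes (sex-dependent ICV;
#' HV linear in ICV with a per-diagnosis shift), and white-matter
#' hyperintensity volume (log-normal percent of ICV, increasing with
#' age). Each biomarker's standardized residual variation is driven by
#' the corresponding column of `signal`, which [generate_cohort()] uses
#' to couple biomarkers to cognitive performance at the configured
#' standardized effect sizes; a zero matrix gives the pure location
#' model.
#'
#' @param signal n x 5 numeric matrix with columns `amyloid`,
#'   `tau_meta`, `tau_ec`, `hv`, `wmh` of (approximately) standardized
#'   pathology signals, or `NULL` for independent standard-normal
#'   signals.
#' @param age,sex,diagnosis participant vectors (`sex` coded "F"/"M",
#'   `diagnosis` one of CU/MCI/Dementia).
#' @param config a [cohort_config()] object.
#' @return data frame with columns `amyloid_suvr`, `tau_meta_suvr`,
#'   `tau_ec_suvr`, `hv`, `icv`, `wmh`.
#' @export
simulate_biomarkers <- function(signal, age, sex, diagnosis,
                                config = cohort_config()) {
  n <- length(age)
  nm <- c("amyloid", "tau_meta", "tau_ec", "hv", "wmh")
  if (is.null(signal)) {
    signal <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, nm))
  }
  stopifnot(is.matrix(signal), nrow(signal) == n, all(nm %in% colnames(signal)))
  diagnosis <- as.character(diagnosis)
  agestd <- (age - config$age$mean[["CU"]]) / 10

  suvr <- function(name) {
    bm <- config$biomarkers[[name]]
    dec <- .ln_decompose(bm, config)
    exp(dec$m0[diagnosis] + dec$lambda * agestd +
          dec$s_u[diagnosis] * signal[, name])
  }
  amyloid <- suvr("amyloid")
  tau_meta <- suvr("tau_meta")
  tau_ec <- suvr("tau_ec")

  hvp <- config$biomarkers$hv
  sex <- as.character(sex)
  icv <- stats::rnorm(n, hvp$icv_mean[sex], hvp$icv_sd[sex])
  icv <- pmax(icv, 9e5)
  hv <- hvp$intercept[sex] + hvp$slope * icv + hvp$shift[diagnosis] +
    hvp$resid_sd * signal[, "hv"]
  hv <- pmax(hv, 1000)

  wmhp <- config$biomarkers$wmh
  dec_w <- .ln_decompose_wmh(wmhp, config)
  ln_pct <- dec_w$m0[diagnosis] + dec_w$lambda * agestd +
    dec_w$s_u[diagnosis] * signal[, "wmh"]
  ln_pct <- pmin(ln_pct, 4.5)  # keep WMH below ICV
  wmh <- icv * exp(ln_pct) / 100

  data.frame(amyloid_suvr = unname(amyloid), tau_meta_suvr = unname(tau_meta),
             tau_ec_suvr = unname(tau_ec), hv = unname(hv),
             icv = unname(icv), wmh = unname(wmh))
}

# Decompose a SUVR biomarker's per-diagnosis log-scale variance into an
# age component (fraction age_frac of the CU log-variance) and a
# residual signal component, re-centering locations so that the
# natural-scale mean/SD targets are preserved given the configured age
# distributions.
.ln_decompose <- function(bm, config) {
  lp <- lnorm_params(bm$mean, bm$sd)      # per-diagnosis meanlog/sdlog
  names(lp$meanlog) <- names(lp$sdlog) <- names(bm$mean)
  s_cu <- lp$sdlog[["CU"]]
  v_age_cu <- (config$age$sd[["CU"]] / 10)^2
  lambda <- sqrt(bm$age_frac * s_cu^2 / v_age_cu)
  diags <- names(bm$mean)
  v_age <- (config$age$sd[diags] / 10)^2
  s_u <- sqrt(pmax(lp$sdlog[diags]^2 - lambda^2 * v_age, 0.05 * lp$sdlog[diags]^2))
  mu_age <- (config$age$mean[diags] - config$age$mean[["CU"]]) / 10
  m0 <- lp$meanlog[diags] - lambda * mu_age
  list(m0 = m0, lambda = lambda, s_u = s_u)
}

.ln_decompose_wmh <- function(bm, config) {
  s_cu <- bm$ln_sd[["CU"]]
  v_age_cu <- (config$age$sd[["CU"]] / 10)^2
  lambda <- sqrt(bm$age_frac * s_cu^2 / v_age_cu)
  diags <- names(bm$ln_mean)
  v_age <- (config$age$sd[diags] / 10)^2
  s_u <- sqrt(pmax(bm$ln_sd[diags]^2 - lambda^2 * v_age, 0.05 * bm$ln_sd[diags]^2))
  mu_age <- (config$age$mean[diags] - config$age$mean[["CU"]]) / 10
  m0 <- bm$ln_mean[diags] - lambda * mu_age
  list(m0 = m0, lambda = lambda, s_u = s_u)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [cohort_config()]: diagnosis labels
#' (multinomial at the configured case mix), demographics, correlated
#' latent memory/speed abilities (with negative age loadings), item-level
#' SLS and Symbols sessions, and imaging biomarkers coupled to realized
#' cognitive performance so that the covariate-adjusted standardized
#' association between each prepared biomarker and the CU-standardized
#' MTD-SBCr equals the configured target in expectation. The coupling
#' works on the covariate-residualized composite, so the targets are
#' recovered exactly (not attenuated by test measurement error); with a
#' mixed case mix the per-diagnosis biomarker location shifts add
#' further association on top of the configured within-cohort effect,
#' as in real data.
#'
#' All randomness flows from `config$seed`; identical configurations
#' produce field-for-field identical cohorts.
#'
#' @param config a [cohort_config()] object.
#' @return object of class `mtd_cohort`: a list with `participants`
#'   (data frame of demographics, diagnosis and latent abilities),
#'   `sls` and `symbols` (item-level session components as in
#'   [simulate_sls_sessions()] / [simulate_symbols_sessions()]),
#'   `imaging` (data frame) and the generating `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n
  diags <- c("CU", "MCI", "Dementia")
  diagnosis <- sample(diags, n, replace = TRUE,
                      prob = config$diagnosis_proportions[diags])

  age <- stats::rnorm(n, config$age$mean[diagnosis], config$age$sd[diagnosis])
  age <- pmin(pmax(age, config$age$range[1]), config$age$range[2])
  sex <- ifelse(stats::runif(n) < config$female_prop, "F", "M")
  education <- round(stats::rnorm(n, config$education$mean[diagnosis],
                                  config$education$sd[diagnosis]))
  education <- pmin(pmax(education, config$education$range[1]),
                    config$education$range[2])

  agestd <- (age - config$age$mean[["CU"]]) / 10
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- config$latent_cor
  e_mem <- z1
  e_spd <- rho * z1 + sqrt(1 - rho^2) * z2
  latent_memory <- config$memory$mean[diagnosis] +
    config$memory$age_slope * agestd + config$memory$sd[diagnosis] * e_mem
  latent_speed <- config$speed$mean[diagnosis] +
    config$speed$age_slope * agestd + config$speed$sd[diagnosis] * e_spd

  sls <- simulate_sls_sessions(latent_memory, config$sls)
  symbols <- simulate_symbols_sessions(latent_speed, config$symbols)

  signal <- .cognition_coupled_signal(sls, symbols, diagnosis, agestd, sex,
                                      education, config)
  imaging <- simulate_biomarkers(signal, age, sex, diagnosis, config)

  participants <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, education_years = as.numeric(education),
    diagnosis = diagnosis,
    latent_memory = unname(latent_memory),
    latent_speed = unname(latent_speed)
  )
  structure(list(participants = participants, sls = sls, symbols = symbols,
                 imaging = imaging, config = config),
            class = "mtd_cohort")
}

# Builds the n x 5 standardized biomarker signal matrix: each column is
# c * ytilde + sqrt(1 - c^2) * noise, where ytilde is the
# covariate-residualized, unit-variance CU-standardized MTD-SBCr and c
# is chosen per biomarker so the adjusted standardized association
# equals the configured target.
.cognition_coupled_signal <- function(sls, symbols, diagnosis, agestd, sex,
                                      education, config) {
  n <- length(diagnosis)
  nm <- c("amyloid", "tau_meta", "tau_ec", "hv", "wmh")
  eps <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(NULL, nm))
  if (all(config$effects == 0)) return(eps)

  sls_sc <- score_sls(sls$spans, sls$correct, sls$delay_correct,
                      sls$delay_presented)
  sym_sc <- suppressWarnings(score_symbols(symbols$correct, symbols$rt))
  sbcr <- compute_mtd_sbcr(sls_sc$sum_of_trials, sym_sc$symaw)
  cu <- diagnosis == "CU"
  ok <- !is.na(sbcr)
  if (sum(cu & ok) < 3 || sum(ok) < 10 || stats::sd(sbcr[cu & ok]) == 0) {
    warning("generate_cohort: too few usable CU scores to couple biomarkers to cognition; effects set to 0 for this cohort")
    return(eps)
  }
  zy <- z_score(sbcr, reference_stats(sbcr, cu, "mtd_sbcr"))
  X <- cbind(1, agestd, as.numeric(sex == "F"), education)
  r <- rep(0, n)
  fit <- stats::lm.fit(X[ok, , drop = FALSE], zy[ok])
  r[ok] <- fit$residuals
  sd_r <- stats::sd(r[ok])
  ytilde <- r / sd_r

  # per-biomarker ratio of residual-signal SD to total CU SD on the
  # scale the association analysis sees (log scale for SUVRs/WMH,
  # residual scale for HV)
  ratio <- c(
    amyloid  = .signal_ratio_suvr(config$biomarkers$amyloid, config),
    tau_meta = .signal_ratio_suvr(config$biomarkers$tau_meta, config),
    tau_ec   = .signal_ratio_suvr(config$biomarkers$tau_ec, config),
    hv       = 1,
    wmh      = .signal_ratio_wmh(config$biomarkers$wmh, config)
  )
  out <- eps
  for (k in nm) {
    cc <- config$effects[[k]] * ratio[[k]] / sd_r
    if (abs(cc) >= 1) {
      stop(sprintf("generate_cohort: configured effect for '%s' is unattainable (|loading| >= 1)", k))
    }
    out[, k] <- cc * ytilde + sqrt(1 - cc^2) * eps[, k]
  }
  out
}

.signal_ratio_suvr <- function(bm, config) {
  dec <- .ln_decompose(bm, config)
  s_cu_total <- lnorm_params(bm$mean[["CU"]], bm$sd[["CU"]])$sdlog
  dec$s_u[["CU"]] / s_cu_total
}

.signal_ratio_wmh <- function(bm, config) {
  dec <- .ln_decompose_wmh(bm, config)
  dec$s_u[["CU"]] / bm$ln_sd[["CU"]]
}

#' @export
print.mtd_cohort <- function(x, ...) {
  tab <- table(x$participants$diagnosis)
  cat(sprintf("Synthetic MTD cohort: %d participants (seed %d)\n",
              nrow(x$participants), x$config$seed))
  print(tab)
  invisible(x)
}
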