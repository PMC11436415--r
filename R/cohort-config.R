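#' Synthetic cohort configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults emulate the structure of a population-based aging cohort
#' enriched for cognitively unimpaired (CU) participants: a 94/5/1
#' CU/MCI/dementia case mix, group-specific age, education and latent
#' cognitive-ability distributions calibrated so that the scored test
#' variables (SLS Sum of Trials, SYM, SYMaw) and imaging biomarkers
#' (amyloid and tau PET SUVRs, hippocampal and intracranial volume,
#' white-matter-hyperintensity volume) reproduce the group means and
#' SDs reported for the validation cohort (see
#' [mcsa_group_summaries]), and configurable standardized
#' biomarker-cognition effects recoverable by [fit_adjusted_association()].
#'
#' @param n number of participants.
#' @param seed integer seed; every random draw in [generate_cohort()]
#'   flows from it.
#' @param diagnosis_proportions named numeric (CU, MCI, Dementia)
#'   summing to 1.
#' @param effects named numeric vector of target standardized adjusted
#'   regression coefficients of each prepared biomarker on the
#'   CU-standardized MTD-SBCr (names `amyloid`, `tau_meta`, `tau_ec`,
#'   `hv`, `wmh`).
#' @param age,education per-diagnosis normal location/scale (lists with
#'   `mean`, `sd`, `range`).
#' @param female_prop proportion of female participants.
#' @param memory,speed latent-ability models: per-diagnosis `mean` and
#'   residual `sd` plus `age_slope` per decade of age (negative by
#'   default so covariate adjustment has non-trivial work).
#' @param latent_cor correlation between the memory and speed residuals.
#' @param sls,symbols,biomarkers test- and biomarker-model parameter
#'   lists; see the package vignette for the meaning and calibration of
#'   each constant.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(
    n = 684,
    seed = 1L,
    diagnosis_proportions = c(CU = 0.94, MCI = 0.05, Dementia = 0.01),
    effects = c(amyloid = -0.15, tau_meta = -0.19, tau_ec = -0.24,
                hv = 0.24, wmh = -0.19),
    age = list(mean = c(CU = 69.890, MCI = 77.0, Dementia = 81.6),
               sd   = c(CU = 11.111, MCI = 10.097, Dementia = 10.097),
               range = c(38, 98)),
    female_prop = 0.497,
    education = list(mean = c(CU = 15.719, MCI = 14.512, Dementia = 14.512),
                     sd   = c(CU = 2.335,  MCI = 2.812,  Dementia = 2.812),
                     range = c(8, 20)),
    memory = list(mean = c(CU = 0, MCI = -1.50, Dementia = -2.30),
                  sd   = c(CU = 0.87, MCI = 1.05, Dementia = 1.05),
                  age_slope = -0.30),
    speed = list(mean = c(CU = 0, MCI = -1.40, Dementia = -2.20),
                 sd   = c(CU = 0.93, MCI = 1.30, Dementia = 1.30),
                 age_slope = -0.25),
    latent_cor = 0.4,
    sls = list(diff_base = -2.65, diff_slope = 0.03, delay_offset = 0.25,
               step_up_all = 4L, step_up_most = 1L, step_down = 2L,
               acc_up = 0.75, acc_down = 0.5),
    symbols = list(rt_mu = 1.095, rt_beta = 0.312, rt_sigma = 0.35,
                   acc_int = 3.7, acc_beta = 0.5),
    biomarkers = list(
      amyloid  = list(mean = c(CU = 1.527, MCI = 1.890, Dementia = 1.890),
                      sd   = c(CU = 0.341, MCI = 0.637, Dementia = 0.637),
                      age_frac = 0.15),
      tau_meta = list(mean = c(CU = 1.197, MCI = 1.389, Dementia = 1.389),
                      sd   = c(CU = 0.098, MCI = 0.374, Dementia = 0.374),
                      age_frac = 0.15),
      tau_ec   = list(mean = c(CU = 1.120, MCI = 1.360, Dementia = 1.360),
                      sd   = c(CU = 0.130, MCI = 0.322, Dementia = 0.322),
                      age_frac = 0.15),
      wmh      = list(ln_mean = c(CU = -0.680, MCI = -0.111, Dementia = -0.111),
                      ln_sd   = c(CU = 0.884,  MCI = 1.047,  Dementia = 1.047),
                      age_frac = 0.15),
      hv       = list(icv_mean = c(F = 1.38e6, M = 1.55e6),
                      icv_sd   = c(F = 1.1e5,  M = 1.2e5),
                      intercept = c(F = 2470, M = 2175),
                      slope = 0.0035,
                      resid_sd = 650,
                      shift = c(CU = 0, MCI = -550, Dementia = -900))
    )) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    diagnosis_proportions = diagnosis_proportions, effects = effects,
    age = age, female_prop = female_prop, education = education,
    memory = memory, speed = speed, latent_cor = latent_cor,
    sls = sls, symbols = symbols, biomarkers = biomarkers
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  p <- cfg$diagnosis_proportions
  if (length(p) != 3 || is.null(names(p)) ||
      !setequal(names(p), c("CU", "MCI", "Dementia"))) {
    stop("cohort_config: diagnosis_proportions must be named CU, MCI, Dementia")
  }
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8) {
    stop("cohort_config: diagnosis_proportions must lie in [0,1] and sum to 1")
  }
  if (cfg$n < 1) stop("cohort_config: n must be >= 1")
  for (blk in c("age", "education", "memory", "speed")) {
    if (any(cfg[[blk]]$sd <= 0)) {
      stop(sprintf("cohort_config: %s sd must be > 0", blk))
    }
  }
  if (cfg$female_prop < 0 || cfg$female_prop > 1) {
    stop("cohort_config: female_prop must lie in [0,1]")
  }
  if (abs(cfg$latent_cor) >= 1) stop("cohort_config: |latent_cor| must be < 1")
  need <- c("amyloid", "tau_meta", "tau_ec", "hv", "wmh")
  if (!all(need %in% names(cfg$effects))) {
    stop("cohort_config: effects must name ", paste(need, collapse = ", "))
  }
  if (any(abs(cfg$effects) >= 0.9)) {
    stop("cohort_config: |effects| must be < 0.9")
  }
  invisible(cfg)
}

# Log-normal location/scale from a natural-scale mean and SD
# (moment inversion; used for SUVR biomarker models).
lnorm_params <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  case mix: CU %.3f / MCI %.3f / Dementia %.3f\n",
              x$diagnosis_proportions[["CU"]],
              x$diagnosis_proportions[["MCI"]],
              x$diagnosis_proportions[["Dementia"]]))
  cat("  target standardized biomarker effects on MTD-SBCr:\n")
  print(round(x$effects, 3))
  invisible(x)
}
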