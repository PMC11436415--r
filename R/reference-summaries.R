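#' Published group summary statistics for the validation cohort
#'
#' Means, SDs and group sizes reported for the MCSA/ADRC remote-
#' assessment validation cohort (643 cognitively unimpaired vs 41
#' MCI/dementia participants), together with the published Hedge's g
#' effect sizes and 95% CI bounds where given. These summaries are the
#' inputs for reproducing the published effect-size column from summary
#' statistics alone via [hedges_g_from_summary()]; the restricted
#' participant-level data are not distributed.
#'
#' `full_mean`/`full_sd` are the full-sample (n = 684) summaries where
#' published (currently age only, used for internal-consistency
#' checks).
#'
#' @format data frame with one row per characteristic and columns
#'   `variable`, `domain`, `cu_mean`, `cu_sd`, `cu_n`, `imp_mean`,
#'   `imp_sd`, `imp_n`, `pub_g`, `pub_ci_low`, `pub_ci_high`,
#'   `full_mean`, `full_sd`.
#' @return data frame (invisibly constructed at load time).
#' @export
mcsa_group_summaries <- local({
  row <- function(variable, domain, cu_mean, cu_sd, imp_mean, imp_sd,
                  pub_g, pub_lo, pub_hi, full_mean = NA, full_sd = NA) {
    data.frame(variable = variable, domain = domain,
               cu_mean = cu_mean, cu_sd = cu_sd, cu_n = 643,
               imp_mean = imp_mean, imp_sd = imp_sd, imp_n = 41,
               pub_g = pub_g, pub_ci_low = pub_lo, pub_ci_high = pub_hi,
               full_mean = full_mean, full_sd = full_sd)
  }
  rbind(
    row("age", "demographics", 69.890, 11.111, 77.786, 10.097,
        0.71, 0.40, 1.03, full_mean = 70.363, full_sd = 11.204),
    row("education", "demographics", 15.719, 2.335, 14.512, 2.812,
        -0.51, -0.83, -0.19, full_mean = 15.646, full_sd = 2.381),
    row("mtd_sbcr", "cognition_remote", 107.653, 20.171, 66.314, 25.200,
        -2.02, -2.35, -1.68),
    row("mtd_sbcz", "cognition_remote", 0.000, 1.000, -1.830, 1.057,
        -2.10, -2.44, -1.76),
    row("sls_sum_of_trials", "cognition_remote", 75.833, 17.174, 45.025, 19.265,
        -1.78, -2.11, -1.45),
    row("sym", "cognition_remote", 3.337, 1.067, 5.623, 2.513,
        1.91, 1.57, 2.24),
    row("symaw", "cognition_remote", 31.839, 6.065, 21.289, 10.338,
        -1.65, -1.98, -1.32),
    row("mayo_pacc", "cognition_in_person", 0.000, 1.000, -2.356, 1.368,
        -2.28, -2.64, -1.92),
    row("global_z", "cognition_in_person", 0.000, 1.000, -2.694, 0.923,
        -2.70, -3.12, -2.28),
    row("avlt_sum_of_trials", "cognition_in_person", 66.979, 17.568, 35.289, 11.130,
        -1.83, -2.18, -1.49),
    row("trails_b", "cognition_in_person", 72.472, 34.875, 157.351, 83.977,
        2.17, 1.82, 2.52),
    row("digit_symbol", "cognition_in_person", 52.060, 12.222, 34.179, 9.843,
        -1.47, -1.86, -1.09),
    row("stms", "cognition_in_person", 35.962, 1.905, 29.500, 4.449,
        -3.02, -3.38, -2.67),
    row("amyloid_suvr", "imaging", 1.527, 0.341, 1.890, 0.637,
        0.99, 0.67, 1.32),
    row("tau_meta_suvr", "imaging", 1.197, 0.098, 1.389, 0.374,
        1.45, 1.13, 1.78),
    row("tau_ec_suvr", "imaging", 1.120, 0.130, 1.360, 0.322,
        1.62, 1.29, 1.95),
    row("hv_z", "imaging", -0.283, 0.611, -1.292, 1.023,
        -1.57, -1.90, -1.24),
    row("wmh_pct_ln", "imaging", -0.680, 0.884, -0.111, 1.047,
        0.64, 0.32, 0.95)
  )
})
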