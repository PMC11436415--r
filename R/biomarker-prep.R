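#' Natural-log then reference z-transform
#'
#' Standard preparation for right-skewed positive biomarkers (PET
#' SUVRs): natural log, then z-scoring of the logged values against the
#' reference subgroup. The order matters (log of a z-score is
#' undefined for non-positive values); this function always logs first.
#'
#' @param values positive numeric vector; non-positive entries are set
#'   to `NA` with a warning.
#' @param reference_mask logical vector for the reference subgroup.
#' @param var_name name used in messages.
#' @return numeric vector of z-scores of the logged values.
#' @export
#' @examples
#' ln_z(exp(1:3), rep(TRUE, 3))
ln_z <- function(values, reference_mask, var_name = "biomarker") {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    warning(sprintf("ln_z: %d non-positive value(s) in '%s' set to NA",
                    sum(bad), var_name))
    values[bad] <- NA_real_
  }
  lv <- log(values)
  z_score(lv, reference_stats(lv, reference_mask, var_name))
}

#' ICV-adjusted hippocampal volume z-score
#'
#' Head size confounds raw hippocampal volume (HV), so HV is
#' residualized on intracranial volume (ICV) with sex-specific linear
#' regressions before z-scoring. The regression lines are fit on the
#' reference subgroup only (mirroring the reference-group z-scoring
#' convention and avoiding contamination of the normative slope by
#' atrophied cases) and applied to all records of that sex; the
#' residuals are then z-scored against the reference subgroup. No log
#' step is applied: residuals are signed.
#'
#' @param hv,icv positive numeric vectors (volumes, same units).
#' @param sex character/factor vector; records with missing sex get
#'   missing output.
#' @param reference_mask logical vector for the reference subgroup.
#' @return list with `residual` (raw residuals) and `z`
#'   (reference-standardized residuals).
#' @export
adjust_hv_icv <- function(hv, icv, sex, reference_mask) {
  n <- length(hv)
  stopifnot(length(icv) == n, length(sex) == n, length(reference_mask) == n)
  sex <- as.character(sex)
  resid <- rep(NA_real_, n)
  for (s in unique(sex[!is.na(sex)])) {
    in_sex <- !is.na(sex) & sex == s
    fit_rows <- in_sex & reference_mask & !is.na(hv) & !is.na(icv)
    if (sum(fit_rows) < 3) {
      stop(sprintf("adjust_hv_icv: fewer than 3 reference records for sex '%s'", s))
    }
    fit <- stats::lm.fit(cbind(1, icv[fit_rows]), hv[fit_rows])
    coefs <- fit$coefficients
    resid[in_sex] <- hv[in_sex] - (coefs[1] + coefs[2] * icv[in_sex])
  }
  z <- z_score(resid, reference_stats(resid, reference_mask, "hv_residual"))
  list(residual = resid, z = z)
}

#' Log percent white-matter-hyperintensity volume
#'
#' WMH volume is expressed as a percentage of ICV (100 * wmh / icv),
#' natural-log transformed to correct its strong right skew, and
#' z-scored against the reference subgroup. Records with `wmh >= icv`
#' are set to missing with a warning.
#'
#' @param wmh,icv positive numeric volume vectors (same units).
#' @param reference_mask logical vector for the reference subgroup.
#' @param ln_floor values of ln-percent below this floor are flagged in
#'   the returned `flagged` vector (default -12, i.e. vanishing WMH).
#' @return list with `ln_pct` (log percent), `z` and `flagged`.
#' @export
wmh_percent_ln <- function(wmh, icv, reference_mask, ln_floor = -12) {
  bad <- !is.na(wmh) & !is.na(icv) & (wmh >= icv | wmh <= 0 | icv <= 0)
  if (any(bad)) {
    warning(sprintf("wmh_percent_ln: %d record(s) with wmh >= icv or non-positive volumes set to NA", sum(bad)))
  }
  pct <- 100 * wmh / icv
  pct[bad] <- NA_real_
  ln_pct <- log(pct)
  list(ln_pct = ln_pct,
       z = z_score(ln_pct, reference_stats(ln_pct, reference_mask, "wmh_pct_ln")),
       flagged = !is.na(ln_pct) & ln_pct < ln_floor)
}

#' Prepare all imaging biomarkers for analysis
#'
#' Applies the standard transformations to a table of derived imaging
#' values: log/z for the three SUVRs, sex-specific ICV adjustment and
#' z for hippocampal volume, and log-percent/z for WMH, all referenced
#' to the designated subgroup.
#'
#' @param imaging data frame with columns `amyloid_suvr`,
#'   `tau_meta_suvr`, `tau_ec_suvr`, `hv`, `icv`, `wmh`.
#' @param sex character vector, same length.
#' @param reference_mask logical vector for the reference subgroup.
#' @return data frame with columns `amyloid_z`, `tau_meta_z`,
#'   `tau_ec_z`, `hv_adj_z`, `wmh_pct_ln`, `wmh_pct_ln_z`.
#' @export
prepare_biomarkers <- function(imaging, sex, reference_mask) {
  need <- c("amyloid_suvr", "tau_meta_suvr", "tau_ec_suvr", "hv", "icv", "wmh")
  miss <- setdiff(need, names(imaging))
  if (length(miss) > 0) {
    stop("prepare_biomarkers: missing columns: ", paste(miss, collapse = ", "))
  }
  wmh <- wmh_percent_ln(imaging$wmh, imaging$icv, reference_mask)
  data.frame(
    amyloid_z = ln_z(imaging$amyloid_suvr, reference_mask, "amyloid_suvr"),
    tau_meta_z = ln_z(imaging$tau_meta_suvr, reference_mask, "tau_meta_suvr"),
    tau_ec_z = ln_z(imaging$tau_ec_suvr, reference_mask, "tau_ec_suvr"),
    hv_adj_z = adjust_hv_icv(imaging$hv, imaging$icv, sex, reference_mask)$z,
    wmh_pct_ln = wmh$ln_pct,
    wmh_pct_ln_z = wmh$z
  )
}
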