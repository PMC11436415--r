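#' Reference-subgroup summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and count of the
#' non-missing values of `values` restricted to the designated reference
#' subgroup. All z-standardization in this package is referenced to a
#' subgroup (by default the cognitively unimpaired participants) rather
#' than to the full sample, so that scores of impaired participants are
#' expressed on the unimpaired scale.
#'
#' @param values numeric vector; `NA` allowed.
#' @param reference_mask logical vector, same length, `TRUE` for rows in
#'   the reference subgroup.
#' @param var_name variable name used in error messages.
#' @return list with elements `mean`, `sd`, `n`.
#' @export
#' @examples
#' reference_stats(c(1, 2, 3, 100), c(TRUE, TRUE, TRUE, FALSE))
reference_stats <- function(values, reference_mask, var_name = "variable") {
  stopifnot(length(values) == length(reference_mask))
  ref <- values[reference_mask & !is.na(values)]
  if (length(ref) < 2) {
    stop(sprintf("reference_stats: fewer than 2 non-missing reference values for '%s'", var_name))
  }
  s <- stats::sd(ref)
  if (!is.finite(s) || s <= 0) {
    stop(sprintf("reference_stats: zero variance in reference subgroup for '%s'", var_name))
  }
  list(mean = mean(ref), sd = s, n = length(ref))
}

#' Z-score against reference statistics
#'
#' @param x numeric vector.
#' @param ref list with `mean` and `sd` (see [reference_stats()]).
#' @return numeric vector of z-scores.
#' @export
z_score <- function(x, ref) {
  (x - ref$mean) / ref$sd
}

#' Reference-standardized z-score composite
#'
#' Averages per-variable z-scores computed against reference-subgroup
#' means/SDs, with an optional sign flip per variable (used to invert
#' speed scores where lower raw values mean better performance). The
#' composite is missing whenever any constituent is missing. By default
#' the averaged composite is itself re-standardized against the reference
#' subgroup, so the composite has mean 0 and SD 1 among reference
#' participants (the convention used for MTD-SBCz, Mayo-PACC and
#' global-cognition z-scores).
#'
#' @param subscores data frame (or named list of equal-length numeric
#'   vectors) of raw constituent scores.
#' @param refs named list of reference statistics, one entry per
#'   constituent (each a list with `mean`, `sd`).
#' @param signs named numeric vector of +1/-1, one per constituent.
#' @param reference_mask logical vector marking the reference subgroup;
#'   required when `restandardize = TRUE`.
#' @param restandardize logical; re-z-score the averaged composite
#'   against the reference subgroup (default `TRUE`).
#' @return numeric vector of composite scores (`NA` where any
#'   constituent is missing).
#' @export
z_composite <- function(subscores, refs, signs, reference_mask = NULL,
                        restandardize = TRUE) {
  subscores <- as.data.frame(subscores)
  vars <- names(subscores)
  missing_refs <- setdiff(vars, names(refs))
  if (length(missing_refs) > 0) {
    stop("z_composite: no reference entry for: ", paste(missing_refs, collapse = ", "))
  }
  missing_signs <- setdiff(vars, names(signs))
  if (length(missing_signs) > 0) {
    stop("z_composite: no sign for: ", paste(missing_signs, collapse = ", "))
  }
  if (!all(signs[vars] %in% c(-1, 1))) {
    stop("z_composite: signs must be +1 or -1")
  }
  zmat <- vapply(vars, function(v) {
    signs[[v]] * z_score(subscores[[v]], refs[[v]])
  }, numeric(nrow(subscores)))
  zmat <- matrix(zmat, nrow = nrow(subscores))
  comp <- rowMeans(zmat)            # NA propagates if any constituent is NA
  if (restandardize) {
    if (is.null(reference_mask)) {
      stop("z_composite: reference_mask required when restandardize = TRUE")
    }
    comp <- z_score(comp, reference_stats(comp, reference_mask, "composite"))
  }
  comp
}
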