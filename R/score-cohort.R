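#' Score a cohort end to end
#'
#' Applies [score_sls()], [score_symbols()], [compute_mtd_sbcr()] and
#' the CU-referenced z-composite (MTD-SBCz) to every participant of a
#' synthetic cohort (or to raw session components supplied directly).
#' MTD-SBCz averages the CU-referenced z-scores of SLS Maximum Learning
#' Span, SLS Trials 1-5 Total, SLS Delay and SYM (sign-flipped so
#' higher is better) and is then re-standardized against the CU
#' subgroup, so it has mean 0 and SD 1 among CU participants.
#'
#' @param cohort an `mtd_cohort` from [generate_cohort()].
#' @param reference_mask logical vector designating the z-score
#'   reference subgroup; defaults to `diagnosis == "CU"`.
#' @return data frame, one row per participant: identifiers and
#'   demographics, `sls_t15_total`, `sls_delay`, `sls_sum_of_trials`,
#'   `sls_max_span`, `sym_n_correct`, `sym`, `accuracy_weight`,
#'   `symaw`, `mtd_sbcr`, `mtd_sbcz`.
#' @export
score_cohort <- function(cohort, reference_mask = NULL) {
  stopifnot(inherits(cohort, "mtd_cohort"))
  pp <- cohort$participants
  if (is.null(reference_mask)) reference_mask <- pp$diagnosis == "CU"
  sls <- score_sls(cohort$sls$spans, cohort$sls$correct,
                   cohort$sls$delay_correct, cohort$sls$delay_presented)
  sym <- suppressWarnings(score_symbols(cohort$symbols$correct, cohort$symbols$rt))
  derive_scores(pp, sls, sym, reference_mask)
}

#' Score participants from summary-level columns
#'
#' Ingestion path for exports that carry pre-computed per-test summary
#' variables instead of item logs. Requires columns
#' `sls_t15_total`, `sls_delay`, `sls_max_span`, `sym`, `sym_n_correct`
#' and (for the composites) `diagnosis`. Produces the same derived
#' variables as [score_cohort()].
#'
#' @param data data frame, one row per participant.
#' @param reference_mask logical vector designating the z-score
#'   reference subgroup; defaults to `diagnosis == "CU"`.
#' @return data frame of derived scores (see [score_cohort()]).
#' @export
score_summary <- function(data, reference_mask = NULL) {
  need <- c("sls_t15_total", "sls_delay", "sls_max_span", "sym", "sym_n_correct")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("score_summary: missing required columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(reference_mask)) {
    if (!"diagnosis" %in% names(data)) {
      stop("score_summary: need a diagnosis column or an explicit reference_mask")
    }
    reference_mask <- data$diagnosis == "CU"
  }
  sls <- sls_scores_from_summary(data$sls_t15_total, data$sls_delay,
                                 data$sls_max_span)
  sym <- symbols_scores_from_summary(data$sym, data$sym_n_correct)
  derive_scores(data, sls, sym, reference_mask)
}

#' Score participants from long item-level data
#'
#' Ingestion path for item logs in long format: one row per item with
#' columns `participant_id`, `test` ("sls" or "symbols"), `trial`
#' (1-5 or "delay" for SLS; 1-4 for Symbols), `correct` (0/1) and
#' `rt_seconds` (Symbols only). SLS spans are recovered as the number
#' of item rows per learning trial, and the delay-presented count as
#' the number of delay rows. Produces identical derived scores to the
#' summary path on equivalent data.
#'
#' @param items long-format data frame of item records.
#' @param participants data frame with `id` and `diagnosis` columns
#'   (plus any demographics to carry through).
#' @param reference_mask optional logical vector over `participants`.
#' @return data frame of derived scores (see [score_cohort()]).
#' @export
score_long <- function(items, participants, reference_mask = NULL) {
  need <- c("participant_id", "test", "trial", "correct")
  miss <- setdiff(need, names(items))
  if (length(miss) > 0) {
    stop("score_long: missing required columns: ", paste(miss, collapse = ", "))
  }
  ids <- participants$id
  if (is.null(reference_mask)) reference_mask <- participants$diagnosis == "CU"

  sls_items <- items[items$test == "sls", ]
  sym_items <- items[items$test == "symbols", ]

  one_sls <- function(pid) {
    d <- sls_items[sls_items$participant_id == pid, ]
    learn <- d[d$trial != "delay", ]
    dl <- d[d$trial == "delay", ]
    spans <- as.integer(table(factor(learn$trial, levels = as.character(1:5))))
    corr <- as.integer(tapply(learn$correct,
                              factor(learn$trial, levels = as.character(1:5)),
                              sum))
    c(spans, corr, nrow(dl), sum(dl$correct))
  }
  m <- t(vapply(ids, one_sls, numeric(12)))
  sls <- score_sls(m[, 1:5, drop = FALSE], m[, 6:10, drop = FALSE],
                   m[, 12], m[, 11])

  one_sym <- function(pid) {
    d <- sym_items[sym_items$participant_id == pid, ]
    if (nrow(d) != 48) {
      stop(sprintf("score_long: participant %s has %d symbols items, expected 48",
                   pid, nrow(d)))
    }
    c(d$correct, d$rt_seconds)
  }
  sm <- t(vapply(ids, one_sym, numeric(96)))
  sym <- suppressWarnings(score_symbols(sm[, 1:48, drop = FALSE],
                                        sm[, 49:96, drop = FALSE]))
  derive_scores(participants, sls, sym, reference_mask)
}

# Shared tail of the three ingestion paths: assemble derived variables
# and the two composites.
derive_scores <- function(meta, sls, sym, reference_mask) {
  out <- data.frame(
    sls_t15_total = sls$trials_1_5_total,
    sls_delay = sls$delay,
    sls_sum_of_trials = sls$sum_of_trials,
    sls_max_span = sls$max_learning_span,
    sym_n_correct = sym$n_correct,
    sym = sym$sym,
    accuracy_weight = sym$accuracy_weight,
    symaw = sym$symaw
  )
  keep <- intersect(c("id", "age", "sex", "education_years", "diagnosis"),
                    names(meta))
  out <- cbind(meta[, keep, drop = FALSE], out)
  out$mtd_sbcr <- compute_mtd_sbcr(out$sls_sum_of_trials, out$symaw)
  refs <- list(
    sls_max_span = reference_stats(out$sls_max_span, reference_mask, "sls_max_span"),
    sls_t15_total = reference_stats(out$sls_t15_total, reference_mask, "sls_t15_total"),
    sls_delay = reference_stats(out$sls_delay, reference_mask, "sls_delay"),
    sym = reference_stats(out$sym, reference_mask, "sym")
  )
  out$mtd_sbcz <- z_composite(
    out[, c("sls_max_span", "sls_t15_total", "sls_delay", "sym")],
    refs,
    signs = c(sls_max_span = 1, sls_t15_total = 1, sls_delay = 1, sym = -1),
    reference_mask = reference_mask
  )
  rownames(out) <- NULL
  out
}
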