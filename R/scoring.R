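#' Score Stricker Learning Span (SLS) sessions
#'
#' The SLS is a computer-adaptive word-list learning test: five learning
#' trials (trial 1 presents 8 words; subsequent spans adapt within 2-23
#' words) each followed by four-choice recognition, plus a delay trial
#' over all words presented on any learning trial. Derived scores are
#' the Trials 1-5 total, the Delay total, their sum (Sum of Trials, the
#' primary outcome) and the maximum learning span reached on trials 1-5.
#'
#' @param trial_spans integer vector of 5 spans (words presented on
#'   trials 1-5), or an n x 5 matrix of sessions.
#' @param trial_correct integer vector/matrix of words correctly
#'   recognized per trial, same shape as `trial_spans`.
#' @param delay_correct integer (vector): words correct on the delay trial.
#' @param delay_presented optional integer (vector): unique words
#'   presented across trials 1-5 (checked to be at least the maximum
#'   span and at least `delay_correct` when supplied).
#' @return data frame with columns `trials_1_5_total`, `delay`,
#'   `sum_of_trials`, `max_learning_span`, one row per session.
#' @export
#' @examples
#' score_sls(c(8, 9, 10, 11, 12), c(8, 9, 10, 11, 12), delay_correct = 24)
score_sls <- function(trial_spans, trial_correct, delay_correct,
                      delay_presented = NULL) {
  spans <- .as_trial_matrix(trial_spans, "trial_spans")
  corr  <- .as_trial_matrix(trial_correct, "trial_correct")
  if (!all(dim(spans) == dim(corr))) {
    stop("score_sls: trial_spans and trial_correct have different shapes")
  }
  n <- nrow(spans)
  delay_correct <- .recycle1(delay_correct, n, "delay_correct")

  if (anyNA(spans) || any(spans < 2 | spans > 23)) {
    stop("score_sls: trial_spans must all lie in [2, 23]")
  }
  if (any(spans[, 1] != 8)) {
    stop("score_sls: trial_spans[1] must be 8 (fixed first-trial span)")
  }
  if (anyNA(corr) || any(corr < 0) || any(corr > spans)) {
    stop("score_sls: trial_correct must satisfy 0 <= trial_correct <= trial_spans")
  }
  if (anyNA(delay_correct) || any(delay_correct < 0)) {
    stop("score_sls: delay_correct must be non-negative")
  }
  max_span <- apply(spans, 1, max)
  if (!is.null(delay_presented)) {
    delay_presented <- .recycle1(delay_presented, n, "delay_presented")
    if (any(delay_presented < max_span)) {
      stop("score_sls: delay_presented must be >= max(trial_spans)")
    }
    if (any(delay_correct > delay_presented)) {
      stop("score_sls: delay_correct must be <= delay_presented")
    }
  }
  t15 <- rowSums(corr)
  data.frame(
    trials_1_5_total  = as.integer(t15),
    delay             = as.integer(delay_correct),
    sum_of_trials     = as.integer(t15 + delay_correct),
    max_learning_span = as.integer(max_span)
  )
}

#' Symbols Test accuracy weighting
#'
#' Step-function weight (1-5) applied to the rescaled Symbols Test
#' response time when forming SYMaw. Accuracy on the 48-item Symbols
#' Test is strongly ceiling-skewed, so the weight discriminates mainly
#' near the top of the scale: 1 for fewer than 35 correct; 2 for 35-41;
#' 3 for 42; 4 for 43; 4.25 for 44; 4.5 for 45; 4.75 for 46; 5 for 47-48.
#'
#' @param n_correct integer vector of correct-item counts in 0-48.
#' @return numeric vector of weights.
#' @export
#' @examples
#' accuracy_weight(c(20, 35, 42, 44, 48))
accuracy_weight <- function(n_correct) {
  if (anyNA(n_correct) || any(n_correct < 0 | n_correct > 48) ||
      any(n_correct != floor(n_correct))) {
    stop("accuracy_weight: n_correct must be whole numbers in [0, 48]")
  }
  w <- numeric(length(n_correct))
  w[n_correct < 35] <- 1
  w[n_correct >= 35 & n_correct <= 41] <- 2
  w[n_correct == 42] <- 3
  w[n_correct == 43] <- 4
  w[n_correct == 44] <- 4.25
  w[n_correct == 45] <- 4.5
  w[n_correct == 46] <- 4.75
  w[n_correct >= 47] <- 5
  w
}

#' Score Symbols Test sessions from item-level data
#'
#' The Symbols Test presents 48 symbol-matching items (four sequential
#' 12-item trials). SYM is the mean response time in seconds over
#' correct items. SYMaw rescales SYM as (10 - SYM), floors it at 0 for
#' SYM of 10 s or more, and multiplies by the [accuracy_weight()] step
#' function so that low accuracy discounts fast-but-inaccurate
#' responding.
#'
#' Sessions with zero correct items have undefined SYM; they are
#' returned as missing (never fabricated as 0) with a warning.
#'
#' @param correct logical vector of 48 item outcomes, or an n x 48 matrix.
#' @param rt_seconds positive numeric vector/matrix of response times,
#'   same shape.
#' @return data frame with columns `n_correct`, `sym`,
#'   `accuracy_weight`, `symaw`, one row per session.
#' @export
#' @examples
#' score_symbols(rep(TRUE, 48), rep(3, 48))
score_symbols <- function(correct, rt_seconds) {
  corr <- .as_item_matrix(correct, "correct")
  rt   <- .as_item_matrix(rt_seconds, "rt_seconds")
  if (!all(dim(corr) == dim(rt))) {
    stop("score_symbols: correct and rt_seconds have different shapes")
  }
  if (anyNA(rt) || any(rt <= 0)) {
    stop("score_symbols: rt_seconds must be strictly positive")
  }
  corr <- corr > 0  # accept 0/1 numeric
  n_correct <- rowSums(corr)
  sym <- rowSums(rt * corr) / n_correct
  zero <- n_correct == 0
  if (any(zero)) {
    warning(sprintf("score_symbols: %d session(s) with zero correct items; SYM/SYMaw set to NA", sum(zero)))
    sym[zero] <- NA_real_
  }
  w <- accuracy_weight(n_correct)
  symaw <- pmax(0, 10 - sym) * w
  data.frame(
    n_correct = as.integer(n_correct),
    sym = sym,
    accuracy_weight = w,
    symaw = symaw
  )
}

#' Symbols scores from pre-computed summaries
#'
#' Some data exports carry only the summary variables (mean correct-item
#' response time and number correct) rather than item logs; this path
#' produces the same derived scores as [score_symbols()].
#'
#' @param sym mean correct-item response time in seconds (`NA` allowed).
#' @param n_correct correct-item count in 0-48.
#' @return data frame as in [score_symbols()].
#' @export
symbols_scores_from_summary <- function(sym, n_correct) {
  if (any(!is.na(sym) & sym <= 0)) {
    stop("symbols_scores_from_summary: sym must be positive")
  }
  w <- accuracy_weight(n_correct)
  data.frame(
    n_correct = as.integer(n_correct),
    sym = sym,
    accuracy_weight = w,
    symaw = pmax(0, 10 - sym) * w
  )
}

#' SLS scores from pre-computed summaries
#'
#' @param trials_1_5_total words correct over trials 1-5.
#' @param delay words correct on the delay trial.
#' @param max_learning_span maximum span reached on trials 1-5.
#' @return data frame as in [score_sls()].
#' @export
sls_scores_from_summary <- function(trials_1_5_total, delay, max_learning_span) {
  if (any(trials_1_5_total < 0, na.rm = TRUE) || any(delay < 0, na.rm = TRUE)) {
    stop("sls_scores_from_summary: totals must be non-negative")
  }
  data.frame(
    trials_1_5_total = trials_1_5_total,
    delay = delay,
    sum_of_trials = trials_1_5_total + delay,
    max_learning_span = max_learning_span
  )
}

#' Raw MTD screening battery composite (MTD-SBCr)
#'
#' Sum of the SLS Sum of Trials and SYMaw. Unlike z-score composites the
#' raw composite is interpretable independently of any study-specific
#' reference sample. Missing whenever either constituent is missing.
#'
#' @param sum_of_trials SLS Sum of Trials.
#' @param symaw accuracy-weighted Symbols score.
#' @return numeric vector.
#' @export
#' @examples
#' compute_mtd_sbcr(74, 35)
compute_mtd_sbcr <- function(sum_of_trials, symaw) {
  out <- sum_of_trials + symaw
  out[is.na(sum_of_trials) | is.na(symaw)] <- NA_real_
  out
}

# ---- internal shape helpers -------------------------------------------------

.as_trial_matrix <- function(x, name) {
  if (is.matrix(x)) {
    if (ncol(x) != 5) stop(sprintf("score_sls: %s must have 5 columns (trials)", name))
    return(x)
  }
  if (length(x) != 5) stop(sprintf("score_sls: %s must have length 5", name))
  matrix(x, nrow = 1)
}

.as_item_matrix <- function(x, name) {
  if (is.matrix(x)) {
    if (ncol(x) != 48) stop(sprintf("score_symbols: %s must have 48 columns (items)", name))
    return(x)
  }
  if (length(x) != 48) stop(sprintf("score_symbols: %s must have exactly 48 items", name))
  matrix(x, nrow = 1)
}

.recycle1 <- function(x, n, name) {
  if (length(x) == 1) return(rep(x, n))
  if (length(x) != n) stop(sprintf("%s has length %d, expected %d", name, length(x), n))
  x
}
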