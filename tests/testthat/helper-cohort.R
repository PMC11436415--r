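# Shared synthetic cohorts, built once per test run and memoized.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n, seed, ...) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(cohort_config(n = n, seed = seed, ...))
  }
  .cohort_cache[[key]]
}

cached_scored <- function(n, seed, ...) {
  key <- paste0("s", n, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- score_cohort(cached_cohort(n, seed, ...))
  }
  .cohort_cache[[key]]
}

# Brute-force Spearman oracle: explicit average (mid) ranks and the
# textbook Pearson product-moment formula, independent of rank()/cor().
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Brute-force two-sided Fisher p for a 2x2 table: enumerate every table
# with the observed margins and sum the hypergeometric probabilities
# not exceeding that of the observed table.
brute_fisher <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
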