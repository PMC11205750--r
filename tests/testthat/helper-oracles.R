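# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities from first principles, never calling the package's
# own implementation paths.

# Exhaustive scan over every candidate stump split (midpoints of consecutive
# distinct sorted values); ties in SSE keep the smallest threshold.
brute_stump <- function(x, r) {
  ux <- sort(unique(x))
  best <- list(threshold = -Inf, left = mean(r), right = mean(r),
               sse = sum((r - mean(r))^2))
  if (length(ux) >= 2) {
    for (t in (ux[-length(ux)] + ux[-1]) / 2) {
      l <- mean(r[x <= t])
      rr <- mean(r[x > t])
      sse <- sum((r[x <= t] - l)^2) + sum((r[x > t] - rr)^2)
      if (sse < best$sse - 1e-12) {
        best <- list(threshold = t, left = l, right = rr, sse = sse)
      }
    }
  }
  best
}

# Mann-Whitney AUC with the half-weight tie term, via mid-ranks.
mw_auc <- function(scores, labels) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  rk <- rank(scores)  # mid-ranks for ties
  (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Classical one-way ANOVA from the raw between/within sum-of-squares
# formulas.
brute_anova <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Small cohort used by several feature/sweep tests: 4 patients, 2 contrasts,
# 1 gene, modest grid; any planted effect sits on ADC only.
tiny_cohort <- function(seed = 11, effect = 0, n_patients = 4) {
  es <- matrix(c(0, effect), 1, 2,
               dimnames = list("IDH1", c("T1W", "ADC")))
  generate_cohort(cohort_config(
    n_patients = n_patients, contrasts = c("T1W", "ADC"), genes = "IDH1",
    effect_size = es, biopsy_volume_cm3 = 0.3,
    volume_shape = c(32, 32, 32), seed = seed))
}
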