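# shared fixtures and independent oracles

# brute-force two-sided Fisher exact p for a 2x2 table: enumerate all
# tables with the observed margins and sum the probabilities of those
# no more likely than the observed table (classical definition;
# independent of stats::fisher.test)
fisher_p_brute <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  n <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  p_obs <- prob(a)
  sum(vapply(lo:hi, function(x) {
    p <- prob(x)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# brute-force hypergeometric upper tail P(X >= k), X ~ Hyper(N, K, n)
hyper_tail_brute <- function(k, N, K, n) {
  xs <- k:min(K, n)
  sum(vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# hand two-sample pooled t statistic
t_stat_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# hand one-way ANOVA F from group means and a grand mean
anova_f_hand <- function(groups) {
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  gm <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (sum(ns) - k))
}

# fraction of ground-truth events matched by a detected event within
# a time tolerance
event_recall <- function(gt, det, tol_s = 0.5) {
  if (nrow(gt) == 0L) return(NA_real_)
  mean(vapply(gt$onset_time, function(t0)
    any(abs(det$onset_time - t0) <= tol_s), logical(1)))
}
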