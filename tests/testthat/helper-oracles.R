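# Independent oracles, coded from first principles and kept separate from
# the implementation paths they check.

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (relative slack as in the
# probability-mass ordering convention).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pmf <- vapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  p_obs <- pmf[support == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# Hypergeometric pmf over the enumeration range (to check it sums to 1).
oracle_fisher_pmf <- function(r1, r2, c1) {
  support <- max(0, c1 - r2):min(r1, c1)
  vapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)),
    numeric(1))
}

# Pearson chi-square statistic from the textbook formula, optional Yates
# correction on 2x2 tables.
oracle_chisq_stat <- function(tab, correct = TRUE) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - e)
  if (correct && all(dim(tab) == c(2, 2))) dev <- pmax(dev - 0.5, 0)
  sum(dev^2 / e)
}

# Kruskal-Wallis H with mid-ranks and the standard tie correction.
oracle_kw_stat <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)  # mid-ranks
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Balanced two-way ANOVA sums of squares and F ratios from cell/marginal
# means (brute-force mean contrasts, no model fitting).
oracle_two_way <- function(grid) {
  y <- grid$cfu
  A <- factor(grid$treatment); B <- factor(grid$time_min)
  a <- nlevels(A); b <- nlevels(B); r <- nrow(grid) / (a * b)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- b * r * sum((mA - grand)^2)
  ss_b <- a * r * sum((mB - grand)^2)
  ss_ab <- r * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_e <- sum((y - mAB[cbind(A, B)])^2)
  ss_t <- sum((y - grand)^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (r - 1))
  ms <- c(ss_a, ss_b, ss_ab, ss_e) / df
  list(ss = c(A = ss_a, B = ss_b, AB = ss_ab, error = ss_e, total = ss_t),
       f = ms[1:3] / ms[4], df = df)
}

# Independent Monte-Carlo simulation of the plate-count experiment (not via
# the package's generator) with a pointwise log-ratio estimator of k:
# returns the sampling envelope of the estimates.
oracle_k_envelope <- function(k, n0, dilution, times, reps = 500,
                              probs = c(0.025, 0.975), seed = 99) {
  set.seed(seed)
  est <- replicate(reps, {
    mu <- n0 * dilution * exp(-k * times)
    cts <- rpois(length(times), mu)
    keep <- cts > 0 & times > 0
    mean(-log(cts[keep] / (n0 * dilution)) / times[keep])
  })
  quantile(est, probs)
}

# Exact-integer noiseless fixture: counts halve every 15 min, so every count
# on the 0-60 min grid is an integer and log-linear recovery is exact.
halving_series <- function(n0 = 2e7) {
  times <- c(0, 15, 30, 45, 60)
  survival_series(times, n0 / 2^(times / 15), n0 = n0)
}

default_cfg <- function() irradiance_config(od600 = 1.2)
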