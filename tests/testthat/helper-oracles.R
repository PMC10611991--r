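# Independent oracles used across the suite. These deliberately take a
# different computational route from the package functions they check.

# Wilson bound by numerically inverting the score test: solve
# (phat - p) / sqrt(p (1 - p) / n) = +/- z for p.
oracle_wilson_root <- function(x, n, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  phat <- x / n
  score <- function(p) (phat - p) / sqrt(p * (1 - p) / n)
  lo <- if (x == 0) 0 else
    uniroot(function(p) score(p) - z, c(1e-12, min(phat, 1 - 1e-12)),
            tol = 1e-14)$root
  hi <- if (x == n) 1 else
    uniroot(function(p) score(p) + z, c(max(phat, 1e-12), 1 - 1e-12),
            tol = 1e-14)$root
  c(lo, hi)
}

# Two-sided Fisher p for a 2x2 table by explicit hypergeometric enumeration
# under probability ordering (tables no more probable than the observed one,
# with the conventional 1e-7 relative tolerance on the comparison).
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); tot <- sum(m)
  k <- max(0, r1 + c1 - tot):min(r1, c1)
  pk <- dhyper(k, c1, tot - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, tot - c1, r1)
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# Pearson statistic by direct summation over cells.
oracle_chi2_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# random 2x2 table with positive margins
random_2x2 <- function(max_total = 200) {
  repeat {
    t <- sample(4:max_total, 1)
    cells <- as.vector(stats::rmultinom(1, t, runif(4, 0.05, 1)))
    m <- matrix(cells, 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# small cohort exercising every classification branch
toy_cohort <- function() {
  rec <- reference_cohort()[1:8, ]
  rec$participant_id <- sprintf("T%02d", 1:8)
  rec
}
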