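# Independent oracles, deliberately written from scratch (combinatorics via
# choose(), tests via stats::fisher.test / stats::chisq.test) so they share
# no code with the package internals they check.

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, minimum-likelihood rule.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n1 <- a + b; N <- a + b + c + d
  if (m == 0 || m == N) return(1)
  lo <- max(0, m - (c + d)); hi <- min(m, n1)
  prob <- vapply(lo:hi, function(k) {
    choose(m, k) * choose(N - m, n1 - k) / choose(N, n1)
  }, numeric(1))
  p_obs <- prob[a - lo + 1]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Significance of a table under the stated test-selection rule, routed
# through base R's test functions rather than the package's kernels.
oracle_significant <- function(a, b, c, d, context) {
  N <- a + b + c + d
  min_cell <- min(a, b, c, d)
  fisher <- if (context == "simulation") {
    N <= 50 || min_cell < 5
  } else {
    !(N > 5000 && min_cell >= 50)
  }
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- if (fisher) {
    if (a + c == 0 || b + d == 0) 1 else stats::fisher.test(m)$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }
  if (is.na(p)) p <- 1
  # same exact-tie convention as the package: p equal to alpha is significant,
  # guarded against summation-order ulps
  p <= 0.05 + 1e-9
}

# Brute-force fragility index: enumerate every achievable event split of the
# modified arm and take the minimum distance to a split with the opposite
# significance classification.
oracle_fi <- function(a, b, c, d, context) {
  n1 <- a + b; n2 <- c + d
  if (a < c || (a == c && n1 <= n2)) {
    e_obs <- a; n_mod <- n1; oe <- c; on <- n2
  } else {
    e_obs <- c; n_mod <- n2; oe <- a; on <- n1
  }
  sig <- vapply(0:n_mod, function(e) {
    oracle_significant(e, n_mod - e, oe, on - oe, context)
  }, logical(1))
  flips <- which(sig != sig[e_obs + 1]) - 1
  if (length(flips) == 0) {
    list(fi = n_mod, capped = TRUE, n_mod = n_mod)
  } else {
    list(fi = min(abs(flips - e_obs)), capped = FALSE, n_mod = n_mod)
  }
}

# Random valid tables (both arms non-empty) with totals up to n_max.
random_tables <- function(n, n_max = 60, seed = 1234) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      n1 <- sample(1:(n_max / 2), 1)
      n2 <- sample(1:(n_max / 2), 1)
      a <- sample(0:n1, 1)
      c_ <- sample(0:n2, 1)
      if (n1 + n2 >= 2) break
    }
    out[[i]] <- c(a = a, b = n1 - a, c = c_, d = n2 - c_)
  }
  out
}
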