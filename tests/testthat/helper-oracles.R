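# Independent oracles used across the suite. These are deliberately naive
# implementations (enumeration, brute force) kept separate from the package
# code paths they check.

# Full hypergeometric enumeration of a 2x2 table with fixed margins.
# Two-sided p: sum of probabilities of outcomes no more likely than the
# observed one (minimum-likelihood convention); one-sided: upper tail on
# the [1,1] cell.
enumerate_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  ks <- lo:hi
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  list(
    p_two_sided = sum(p[p <= p_obs * (1 + 1e-7)]),
    p_greater = sum(p[ks >= a])
  )
}

# Brute-force BH step-up: sort, scale by m/i, cumulative min from the top.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Hill number straight from the definition on a frequency vector.
brute_hill <- function(p, q) {
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

# Small, fast simulation config used by integration-style tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, cells_per_donor = 150L, n_genes = 60L, ...)
}

# Donor-level binomial data from the random-intercept logistic model.
sim_masc_data <- function(n_per_group = 20L, n_cells = 1000L,
                          beta0 = -2, beta1 = 0, sigma = 0.5) {
  x <- rep(c(0, 1), each = n_per_group)
  u <- rnorm(length(x), 0, sigma)
  y <- rbinom(length(x), n_cells, plogis(beta0 + beta1 * x + u))
  list(y = y, n = rep(n_cells, length(x)), x = x)
}
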