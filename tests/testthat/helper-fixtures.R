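# Shared fixtures and independent oracles for the test suite.

# Build a monotone two-arm trial with given per-arm counts of patients
# by last observed visit (named vector, names = last visit index as
# character, must include the completer pattern = J).
make_monotone_trial <- function(counts0, counts1, J = 5,
                                visit_times = c(0, 0.5, 1, 3, 6),
                                seed = 1) {
  set.seed(seed)
  n0 <- sum(counts0); n1 <- sum(counts1)
  N <- n0 + n1
  arm <- rep(0:1, c(n0, n1))
  Y <- matrix(rnorm(N * J, 13, 3), N, J)
  R <- matrix(1L, N, J)
  fill <- function(counts, offset) {
    pos <- 1L
    for (k in seq_along(counts)) {
      last <- as.integer(names(counts)[k])
      if (counts[k] == 0) next
      rows <- offset + pos:(pos + counts[k] - 1L)
      if (last < J) R[rows, (last + 1L):J] <<- 0L
      pos <- pos + counts[k]
    }
  }
  fill(counts0, 0L)
  fill(counts1, n0)
  Y[R == 0L] <- NA_real_
  longitudinal_trial(Y, arm, visit_times,
                     age = rnorm(N, 35, 7),
                     art = matrix(rbinom(N * J, 1, 0.8), N, J),
                     R = R)
}

# Brute-force Pearson chi-squared: explicit double loop over cells.
chisq_brute <- function(counts) {
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  stat
}

# Independent conditional-moments oracle via the precision matrix:
# missing-block conditionals read off the full inverse of Sigma.
conditional_moments_oracle <- function(mu, Sigma, obs_idx, y_obs) {
  J <- length(mu)
  m <- setdiff(seq_len(J), obs_idx)
  Lam <- solve(Sigma)
  V <- solve(Lam[m, m, drop = FALSE])
  mean_m <- mu[m] - V %*% Lam[m, obs_idx, drop = FALSE] %*%
    (y_obs - mu[obs_idx])
  list(mean = drop(mean_m), cov = (V + t(V)) / 2)
}

# Random PD covariance matrix of dimension J.
random_pd <- function(J) {
  A <- matrix(rnorm(J * J), J)
  crossprod(A) + diag(J) * 0.1
}

# A small complete random-intercept trial for pipeline tests.
toy_trial <- function(n = 60, seed = 42,
                      params = generative_params(sigma_b = 2,
                                                 sigma_e = 1)) {
  generate_trial(params, n, seed = seed)
}

# Fast Gibbs settings for tests (chains here mix in a few iterations).
fast_gibbs <- function() gibbs_config(burn_in = 50, thin = 10)
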