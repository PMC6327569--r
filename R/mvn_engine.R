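#' Multivariate-normal imputation model parameters
#'
#' One posterior draw of the per-arm imputation model: a coefficient
#' matrix for per-visit regressions of the outcome on baseline
#' covariates, and the visit-by-visit residual covariance.
#'
#' @param beta p x J coefficient matrix (rows: intercept + baseline
#'   covariates; columns: visits).
#' @param Sigma J x J residual covariance, symmetric positive definite.
#' @return object of class `mvn_params`.
#' @export
mvn_params <- function(beta, Sigma) {
  beta <- as.matrix(beta); Sigma <- as.matrix(Sigma)
  if (ncol(beta) != ncol(Sigma)) stop("beta and Sigma disagree on J")
  if (max(abs(Sigma - t(Sigma))) > 1e-10)
    stop("Sigma must be symmetric (tolerance 1e-10)")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive definite")
  structure(list(beta = beta, Sigma = Sigma), class = "mvn_params")
}

#' Gibbs sampler configuration
#'
#' @param burn_in iterations discarded before the first retained draw.
#' @param thin iterations between retained draws (>= 1); successive
#'   retained draws should be effectively independent.
#' @param rng_seed optional integer seed; when `NULL` the current RNG
#'   state is used.
#' @return object of class `gibbs_config`.
#' @export
gibbs_config <- function(burn_in = 200, thin = 100, rng_seed = NULL) {
  stopifnot(burn_in >= 0, thin >= 1)
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 rng_seed = rng_seed), class = "gibbs_config")
}

#' Conditional moments of a multivariate normal
#'
#' Mean and covariance of the missing block of a multivariate normal
#' given observed components: with `o` observed and `m` missing,
#' \deqn{\mu_{m|o} = \mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(y_o - \mu_o),
#' \quad \Sigma_{m|o} = \Sigma_{mm} -
#' \Sigma_{mo}\Sigma_{oo}^{-1}\Sigma_{om}.}
#'
#' @param mu length-J mean vector.
#' @param Sigma J x J covariance, positive definite.
#' @param obs_idx indices (1-based) of the observed components; must be
#'   a nonempty proper subset of `1:J`.
#' @param y_obs observed values, same length as `obs_idx`.
#' @return list with `mean` (length J - length(obs_idx)) and `cov`
#'   (symmetric PSD matrix) of the missing block, plus `miss_idx`.
#' @export
conditional_moments <- function(mu, Sigma, obs_idx, y_obs) {
  J <- length(mu)
  if (length(obs_idx) == 0 || length(obs_idx) >= J)
    stop("obs_idx must be a nonempty proper subset of 1:J")
  m <- setdiff(seq_len(J), obs_idx)
  S_oo <- Sigma[obs_idx, obs_idx, drop = FALSE]
  ch <- tryCatch(chol(S_oo), error = function(e) NULL)
  if (is.null(ch))
    stop("observed-block covariance is singular at visits ",
         paste(obs_idx, collapse = ", "))
  S_mo <- Sigma[m, obs_idx, drop = FALSE]
  # B = S_mo S_oo^{-1}, via the Cholesky factor
  B <- t(backsolve(ch, forwardsolve(t(ch), t(S_mo))))
  cmean <- mu[m] + drop(B %*% (y_obs - mu[obs_idx]))
  ccov <- Sigma[m, m, drop = FALSE] - B %*% t(S_mo)
  ccov <- (ccov + t(ccov)) / 2
  list(mean = cmean, cov = ccov, miss_idx = m)
}

# Upper-triangular square root of a PSD matrix: plain Cholesky with an
# eigendecomposition fallback so a numerically semi-definite
# conditional covariance never aborts an imputation.
chol_psd <- function(cov) {
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(cov, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    ch <- diag(sqrt(ev$values), nrow = nrow(cov)) %*% t(ev$vectors)
  }
  ch
}

# Draw one multivariate normal vector from (mean, cov) with cov PSD.
draw_mvn <- function(mean, cov) {
  drop(mean + t(chol_psd(cov)) %*% stats::rnorm(length(mean)))
}

# Group row indices of a mask by missingness pattern (rows with at
# least one missing cell only).
missing_pattern_groups <- function(R) {
  miss <- which(rowSums(R == 0L) > 0)
  if (!length(miss)) return(list())
  key <- apply(R[miss, , drop = FALSE], 1, paste, collapse = "")
  split(miss, key)
}

#' Posterior draws of the imputation model by Gibbs data augmentation
#'
#' Draws from the joint posterior of the per-visit regression
#' coefficients and the visit covariance of a multivariate-normal
#' outcome model, given partially observed data, under the improper
#' Jeffreys prior \eqn{p(\beta,\Sigma) \propto |\Sigma|^{-(J+1)/2}}.
#' Each iteration alternates an I-step (replace missing cells by draws
#' from their conditional normal given the observed cells and current
#' parameters) and a P-step (draw `Sigma` from its inverse-Wishart full
#' conditional given the completed data, then `beta` from its
#' matrix-normal full conditional). Every `thin`-th draw after
#' `burn_in` is retained.
#'
#' @param Y n x J outcome matrix; missing cells `NA`.
#' @param X n x p design matrix of baseline covariates (include the
#'   intercept column); defaults to intercept only.
#' @param config a [gibbs_config()].
#' @param n_draws number of retained draws.
#' @return list of `n_draws` [mvn_params] objects.
#' @export
gibbs_posterior <- function(Y, X = NULL, config = gibbs_config(),
                            n_draws = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y); J <- ncol(Y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  R <- 1L * !is.na(Y)
  n_complete <- sum(rowSums(R) == J)
  if (n_complete <= J + p)
    stop("need more complete cases (", n_complete,
         ") than visits + covariates (", J + p, ")")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  XtX <- crossprod(X)
  XtX_inv <- chol2inv(chol(XtX))
  A <- chol(XtX_inv)            # A'A = (X'X)^{-1}
  nu <- n - p                   # IW df under the Jeffreys prior
  if (nu <= J) stop("too few patients for the inverse-Wishart draw")

  # initial fill: visit means of the observed values
  Yc <- Y
  vm <- colMeans(Y, na.rm = TRUE)
  for (j in seq_len(J)) Yc[R[, j] == 0L, j] <- vm[j]
  groups <- missing_pattern_groups(R)

  draw_params <- function() {
    Bhat <- XtX_inv %*% crossprod(X, Yc)
    E <- Yc - X %*% Bhat
    S <- crossprod(E)
    Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) {
      chol2inv(chol(S + 1e-8 * diag(J)))
    })
    W <- stats::rWishart(1, nu, Sinv)[, , 1]
    Sigma <- tryCatch(chol2inv(chol(W)), error = function(e) NULL)
    if (is.null(Sigma)) {
      Sigma <- chol2inv(chol(W + 1e-8 * diag(J)))
    }
    Sigma <- (Sigma + t(Sigma)) / 2
    chS <- tryCatch(chol(Sigma), error = function(e) {
      chol(Sigma + 1e-8 * diag(J))
    })
    B <- Bhat + t(A) %*% matrix(stats::rnorm(p * J), p, J) %*% chS
    list(beta = B, Sigma = Sigma)
  }

  impute_step <- function(theta) {
    if (!length(groups)) return(invisible(NULL))
    Mu <- X %*% theta$beta
    for (g in groups) {
      obs <- which(R[g[1], ] == 1L)
      m <- setdiff(seq_len(J), obs)
      S_oo <- theta$Sigma[obs, obs, drop = FALSE]
      ch <- chol(S_oo)
      S_mo <- theta$Sigma[m, obs, drop = FALSE]
      B <- t(backsolve(ch, forwardsolve(t(ch), t(S_mo))))
      ccov <- theta$Sigma[m, m, drop = FALSE] - B %*% t(S_mo)
      chc <- chol_psd((ccov + t(ccov)) / 2)
      resid <- Yc[g, obs, drop = FALSE] - Mu[g, obs, drop = FALSE]
      cmean <- Mu[g, m, drop = FALSE] + resid %*% t(B)
      Z <- matrix(stats::rnorm(length(g) * length(m)), length(g))
      Yc[g, m] <<- cmean + Z %*% chc
    }
  }

  theta <- draw_params()
  out <- vector("list", n_draws)
  total <- config$burn_in + n_draws * config$thin
  k <- 0L
  for (it in seq_len(total)) {
    impute_step(theta)
    theta <- draw_params()
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      out[[k]] <- mvn_params(theta$beta, theta$Sigma)
    }
  }
  out
}
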