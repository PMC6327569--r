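#' Generative parameters for the trial simulator
#'
#' Fixed effects and variance components of the random-intercept model
#' used to simulate longitudinal outcomes:
#' \deqn{Y_{ij} = \beta_0 + \beta_1 trt_i + \beta_2 t_j +
#'   \beta_3 trt_i t_j + b_i + \epsilon_{ij},}
#' with \eqn{b_i \sim N(0, \sigma_b^2)} and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma_e^2)}. The defaults are the
#' study conditions used throughout: \eqn{\beta = (13, 0.75, 0.11,
#' -0.19)} on the square-root CD4 scale, \eqn{\sigma_b = 4.57},
#' \eqn{\sigma_e = 0.20}, five visits at months 0, 0.5, 1, 3, 6 and
#' 1:1 allocation.
#'
#' @param beta length-4 vector `(intercept, treatment, slope per month,
#'   treatment x slope)`.
#' @param sigma_b random-intercept standard deviation.
#' @param sigma_e residual standard deviation.
#' @param visit_times visit months, strictly increasing, length >= 2.
#' @param allocation two-element arm ratio, e.g. `c(1, 1)`.
#' @return object of class `generative_params`.
#' @export
generative_params <- function(beta = c(13, 0.75, 0.11, -0.19),
                              sigma_b = 4.57, sigma_e = 0.20,
                              visit_times = c(0, 0.5, 1, 3, 6),
                              allocation = c(1, 1)) {
  stopifnot(length(beta) == 4, sigma_b >= 0, sigma_e >= 0,
            length(visit_times) >= 2, length(allocation) == 2)
  structure(list(beta = as.numeric(beta), sigma_b = sigma_b,
                 sigma_e = sigma_e,
                 visit_times = as.numeric(visit_times),
                 allocation = as.numeric(allocation)),
            class = "generative_params")
}

#' Dropout model
#'
#' Logistic model for the probability of deviating at each
#' post-baseline visit. Scanning visits in order, a patient still in
#' the study drops at visit `j` with probability
#' `plogis(intercept + slope * (Y[j-1] - Y[1]))`; under MCAR the slope
#' is 0 so dropout is independent of the outcomes, under MAR it
#' depends on the observed change from baseline to the previous visit.
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param intercept logit-scale intercept (calibrate with
#'   [calibrate_rate()]).
#' @param slope logit change per unit change-from-baseline; must be 0
#'   under MCAR. Default 0.5 under MAR.
#' @param monotone if `TRUE` (default) dropout is permanent; otherwise
#'   visits are removed independently with the same probability model.
#' @return object of class `dropout_model`.
#' @export
dropout_model <- function(mechanism = c("MCAR", "MAR"), intercept = -3,
                          slope = NULL, monotone = TRUE) {
  mechanism <- match.arg(toupper(mechanism), c("MCAR", "MAR"))
  if (is.null(slope)) slope <- if (mechanism == "MCAR") 0 else 0.5
  if (mechanism == "MCAR" && slope != 0)
    stop("MCAR requires slope = 0")
  structure(list(mechanism = mechanism, intercept = intercept,
                 slope = slope, monotone = monotone),
            class = "dropout_model")
}

#' Simulate a complete longitudinal trial
#'
#' Generates `n_patients` with the random-intercept model of
#' [generative_params()]. Arms are assigned by deterministic
#' alternation in the allocation ratio (so a 1:1 trial of 200 patients
#' has exactly 100 per arm). Baseline age is drawn `N(35, 7^2)` and a
#' treatment-status indicator starts at Bernoulli(0.8) and switches on
#' monotonely; neither influences the outcome.
#'
#' @param params a [generative_params()].
#' @param n_patients number of patients (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a complete [longitudinal_trial] (mask all ones).
#' @export
generate_trial <- function(params = generative_params(),
                           n_patients = 200, seed = NULL) {
  stopifnot(n_patients >= 2)
  if (!is.null(seed)) set.seed(seed)
  tms <- params$visit_times
  J <- length(tms)
  block <- rep(c(0L, 1L), times = params$allocation)
  arm <- rep_len(rep(block, length.out = sum(params$allocation)),
                 n_patients)
  b <- stats::rnorm(n_patients, 0, params$sigma_b)
  E <- matrix(stats::rnorm(n_patients * J, 0, params$sigma_e),
              n_patients, J)
  M <- outer(arm, tms, function(a, t)
    params$beta[1] + params$beta[2] * a + params$beta[3] * t +
      params$beta[4] * a * t)
  Y <- M + b + E
  age <- stats::rnorm(n_patients, 35, 7)
  art <- matrix(0L, n_patients, J)
  art[, 1] <- stats::rbinom(n_patients, 1, 0.8)
  for (j in 2:J)
    art[, j] <- pmax(art[, j - 1],
                     stats::rbinom(n_patients, 1, 0.1))
  longitudinal_trial(Y, arm, tms, age, art)
}

#' Impose missingness on a complete trial
#'
#' Applies a [dropout_model()] to a complete trial. The baseline visit
#' is never removed. Under the monotone model, once a patient drops at
#' visit `j` all visits `>= j` are missing; the non-monotone variant
#' removes each post-baseline visit independently with the same
#' probability model (using the previous visit's underlying value).
#'
#' @param trial a complete [longitudinal_trial].
#' @param model a [dropout_model()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [longitudinal_trial] with missing cells.
#' @export
impose_dropout <- function(trial, model, seed = NULL) {
  if (any(trial$R == 0L)) stop("trial must be complete")
  if (!is.null(seed)) set.seed(seed)
  Y <- trial$Y
  N <- nrow(Y); J <- ncol(Y)
  R <- matrix(1L, N, J)
  delta <- Y - Y[, 1]           # change from baseline
  if (model$monotone) {
    in_study <- rep(TRUE, N)
    for (j in 2:J) {
      p <- stats::plogis(model$intercept +
                           model$slope * delta[, j - 1])
      drop_now <- in_study & (stats::runif(N) < p)
      if (any(drop_now)) R[drop_now, j:J] <- 0L
      in_study <- in_study & !drop_now
    }
  } else {
    for (j in 2:J) {
      p <- stats::plogis(model$intercept +
                           model$slope * delta[, j - 1])
      R[stats::runif(N) < p, j] <- 0L
    }
  }
  Ym <- Y
  Ym[R == 0L] <- NA_real_
  longitudinal_trial(Ym, trial$arm, trial$visit_times, trial$age,
                     trial$art, trial$patient_id, R = R)
}

#' Calibrate the dropout intercept to a target rate
#'
#' Finds the logit intercept for which the overall fraction of
#' patients not completing the trial equals `target_rate`, by
#' bisection over Monte-Carlo estimates of the achieved rate (a fresh
#' cohort of `n_mc` patients per evaluation, with common random numbers
#' so the rate is monotone in the intercept).
#'
#' @param target_rate desired fraction of non-completers, in `[0, 1)`.
#' @param model a [dropout_model()] template (its intercept is
#'   ignored).
#' @param params a [generative_params()] describing the cohort.
#' @param n_mc simulated patients per evaluation (>= 20000 by
#'   default).
#' @param tol tolerance on the achieved rate (default 0.005, i.e.
#'   half a percentage point).
#' @param seed integer seed for the Monte-Carlo cohort.
#' @return the calibrated intercept (numeric scalar).
#' @export
calibrate_rate <- function(target_rate, model,
                           params = generative_params(),
                           n_mc = 20000, tol = 0.005, seed = 1L) {
  stopifnot(target_rate >= 0, target_rate < 1)
  lo <- -30; hi <- 15
  if (target_rate == 0) return(lo)
  set.seed(seed)
  trial <- generate_trial(params, n_mc)
  U <- matrix(stats::runif(n_mc * (n_visits(trial) - 1)), n_mc)
  delta <- trial$Y - trial$Y[, 1]
  achieved <- function(a) {
    in_study <- rep(TRUE, n_mc)
    for (j in 2:n_visits(trial)) {
      p <- stats::plogis(a + model$slope * delta[, j - 1])
      in_study <- in_study & (U[, j - 1] >= p)
    }
    1 - mean(in_study)
  }
  if (achieved(hi) < target_rate - tol)
    stop("target rate unattainable for this dropout model")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    r <- achieved(mid)
    if (abs(r - target_rate) <= tol / 2) break
    if (r < target_rate) lo <- mid else hi <- mid
  }
  if (abs(achieved(mid) - target_rate) > tol)
    stop("calibration failed to reach the target rate")
  mid
}

#' Generate a fixture trial with prescribed dropout patterns
#'
#' Builds a two-arm trial shaped like a small HIV/TB cohort measured
#' on the square-root CD4 scale over months 0, 0.5, 1, 3 and 6:
#' outcomes rise over time with a large between-patient spread, ART
#' status starts at Bernoulli(0.8) and switches on monotonely, and the
#' monotone dropout patterns are assigned deterministically so that
#' [classify_patterns()] reproduces the requested proportions exactly
#' (largest-remainder rounding per arm; the remainder goes to the
#' completers).
#'
#' @param seed integer seed.
#' @param n_per_arm patients per arm.
#' @param deviation_mix named numeric vector of proportions of
#'   patients whose last observed visit is the given 1-based index,
#'   e.g. `c("2" = 0.11, "3" = 0.06, "4" = 0.14)`; the complement are
#'   completers. May differ by arm if given as a list of two such
#'   vectors (control first).
#' @return a [longitudinal_trial].
#' @export
generate_impi_like <- function(seed = 1L, n_per_arm = 70,
                               deviation_mix = c("2" = 0.11,
                                                 "3" = 0.06,
                                                 "4" = 0.14)) {
  set.seed(seed)
  tms <- c(0, 0.5, 1, 3, 6)
  J <- length(tms)
  if (!is.list(deviation_mix))
    deviation_mix <- list(deviation_mix, deviation_mix)
  N <- 2 * n_per_arm
  arm <- rep(0:1, each = n_per_arm)
  mu_t <- 13 + 0.65 * sqrt(tms) * 2   # rising sqrt-CD4 profile
  b <- stats::rnorm(N, 0, 4.5)
  Y <- matrix(mu_t, N, J, byrow = TRUE) - 0.3 * arm + b +
    matrix(stats::rnorm(N * J, 0, 2), N, J)
  R <- matrix(1L, N, J)
  for (a in 0:1) {
    mix <- deviation_mix[[a + 1]]
    if (sum(mix) > 1) stop("deviation_mix proportions must sum to <= 1")
    raw <- mix * n_per_arm
    cnt <- floor(raw)
    ord <- order(raw - cnt, decreasing = TRUE)
    extra <- round(sum(raw) - sum(cnt))
    if (extra > 0) cnt[ord[seq_len(extra)]] <- cnt[ord[seq_len(extra)]] + 1
    idx <- which(arm == a)
    pos <- 1L
    for (k in seq_along(cnt)) {
      last <- as.integer(names(mix)[k])
      if (cnt[k] == 0) next
      rows <- idx[pos:(pos + cnt[k] - 1L)]
      R[rows, (last + 1L):J] <- 0L
      pos <- pos + cnt[k]
    }
  }
  Y[R == 0L] <- NA_real_
  age <- stats::rnorm(N, 35, 10)
  art <- matrix(0L, N, J)
  art[, 1] <- stats::rbinom(N, 1, 0.8)
  for (j in 2:J)
    art[, j] <- pmax(art[, j - 1], stats::rbinom(N, 1, 0.1))
  longitudinal_trial(Y, arm, tms, age, art, R = R)
}
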