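IMPUTE_METHODS <- c("MAR", "J2R", "CDR", "CR", "LMCF")

#' Imputation specification
#'
#' Which post-deviation assumption to impute under, which arm supplies
#' the reference distribution (for the reference-based methods), and
#' how many imputed datasets to create.
#'
#' @param method one of `"MAR"`, `"J2R"`, `"CDR"`, `"CR"`, `"LMCF"`.
#'   MAR is the de jure (randomized-arm) assumption; the others are
#'   de facto post-deviation assumptions: jump to reference, copy
#'   difference (increments) in reference, copy reference, last mean
#'   carried forward.
#' @param reference_arm arm label whose distribution deviating patients
#'   borrow; ignored (may be `NULL`) for MAR and LMCF.
#' @param K number of imputations; `K >= 2` is required for pooled
#'   inference.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(method = "MAR", reference_arm = NULL, K = 50) {
  method <- match.arg(toupper(method), IMPUTE_METHODS)
  if (method %in% c("J2R", "CDR", "CR") && is.null(reference_arm))
    stop(method, " requires a reference_arm")
  structure(list(method = method, reference_arm = reference_arm,
                 K = as.integer(K)),
            class = "imputation_spec")
}

#' Marginal mean profile under a post-deviation assumption
#'
#' Builds the length-J marginal mean of a deviating patient's joint
#' pre/post-deviation distribution. Up to the deviation visit `n_last`
#' the mean follows the randomized arm; after it:
#' \itemize{
#' \item MAR: continues on the randomized arm's means;
#' \item J2R: jumps to the reference arm's means;
#' \item CDR: continues from the value at deviation with the reference
#'   arm's mean increments;
#' \item CR: the whole profile (pre and post) is the reference arm's;
#' \item LMCF: flattens at the randomized arm's mean at deviation.
#' }
#'
#' @param method one of `"MAR"`, `"J2R"`, `"CDR"`, `"CR"`, `"LMCF"`.
#' @param mu_rand length-J mean profile of the randomized arm.
#' @param mu_ref length-J mean profile of the reference arm.
#' @param n_last 1-based index of the last observed visit.
#' @return length-J mean vector.
#' @export
build_marginal_mean <- function(method, mu_rand, mu_ref, n_last) {
  method <- match.arg(toupper(method), IMPUTE_METHODS)
  J <- length(mu_rand)
  stopifnot(n_last >= 1, n_last <= J)
  post <- if (n_last < J) (n_last + 1L):J else integer(0)
  mu <- mu_rand
  if (method == "CR") return(mu_ref)
  if (length(post)) {
    mu[post] <- switch(method,
      MAR  = mu_rand[post],
      J2R  = mu_ref[post],
      CDR  = mu_rand[n_last] + (mu_ref[post] - mu_ref[n_last]),
      LMCF = mu_rand[n_last])
  }
  mu
}

#' Joint pre/post-deviation covariance under a post-deviation assumption
#'
#' For MAR, LMCF and CDR the patient keeps the randomized arm's
#' covariance. For J2R and CR a composite covariance is assembled: the
#' pre-deviation block (visits up to `n_last`) comes from the arm
#' governing the pre-deviation distribution (randomized arm for J2R,
#' reference arm for CR -- so CR returns the reference covariance
#' unchanged), while the regression coefficients and conditional
#' covariance of the post-deviation visits given the pre-deviation
#' visits are those of the reference arm. With `a` the pre and `b` the
#' post block and `B = \Sigma^{ref}_{ba}(\Sigma^{ref}_{aa})^{-1}`:
#' \deqn{\Sigma^*_{aa} = \Sigma^{pre}_{aa},\quad
#'       \Sigma^*_{ba} = B\,\Sigma^*_{aa},\quad
#'       \Sigma^*_{bb} = \Sigma^{ref}_{b|a} + B\,\Sigma^*_{aa}B'.}
#'
#' @param method one of `"MAR"`, `"J2R"`, `"CDR"`, `"CR"`, `"LMCF"`.
#' @param Sigma_rand J x J covariance of the randomized arm (PD).
#' @param Sigma_ref J x J covariance of the reference arm (PD).
#' @param n_last 1-based index of the last observed visit.
#' @return J x J symmetric positive-definite covariance.
#' @export
build_joint_covariance <- function(method, Sigma_rand, Sigma_ref, n_last) {
  method <- match.arg(toupper(method), IMPUTE_METHODS)
  J <- ncol(Sigma_rand)
  stopifnot(n_last >= 1, n_last <= J)
  if (method %in% c("MAR", "LMCF", "CDR")) return(Sigma_rand)
  if (method == "CR") return(Sigma_ref)
  # J2R composite
  if (n_last == J) return(Sigma_rand)
  a <- seq_len(n_last); b <- (n_last + 1L):J
  S_aa <- Sigma_rand[a, a, drop = FALSE]
  ch <- chol(Sigma_ref[a, a, drop = FALSE])
  Bta <- backsolve(ch, forwardsolve(t(ch),
                                    Sigma_ref[a, b, drop = FALSE]))
  B <- t(Bta)                                   # Sigma_ref regression
  cond <- Sigma_ref[b, b, drop = FALSE] - B %*% Sigma_ref[a, b, drop = FALSE]
  S_ba <- B %*% S_aa
  S_bb <- cond + B %*% S_aa %*% t(B)
  out <- matrix(0, J, J)
  out[a, a] <- S_aa
  out[b, a] <- S_ba
  out[a, b] <- t(S_ba)
  out[b, b] <- (S_bb + t(S_bb)) / 2
  out <- (out + t(out)) / 2
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("composite covariance not positive definite")
  out
}

#' Impute one patient's missing outcomes
#'
#' Completes a patient's outcome vector given one posterior draw of the
#' randomized arm's and the reference arm's imputation models. The
#' patient's covariate-predicted mean profile under each arm is
#' combined with the method's mean and covariance rules into the
#' patient's joint pre/post-deviation distribution, and missing values
#' are drawn from the conditional normal given the observed values.
#' Intermittent missing values (gaps before the last observed visit)
#' are first drawn under the randomized arm's MAR conditional given all
#' observed values; post-deviation values are then drawn under the
#' requested method conditional on the (now complete) history up to the
#' deviation visit. Observed values are never altered.
#'
#' @param y length-J outcome vector with `NA` for missing cells;
#'   baseline must be observed.
#' @param x covariate vector matching the rows of the draws' `beta`.
#' @param draw_rand [mvn_params] draw for the patient's randomized arm.
#' @param draw_ref [mvn_params] draw for the reference arm (pass
#'   `draw_rand` for MAR/LMCF).
#' @param method one of `"MAR"`, `"J2R"`, `"CDR"`, `"CR"`, `"LMCF"`.
#' @return completed length-J numeric vector.
#' @export
impute_patient <- function(y, x, draw_rand, draw_ref = draw_rand,
                           method = "MAR") {
  method <- match.arg(toupper(method), IMPUTE_METHODS)
  J <- length(y)
  if (is.na(y[1])) stop("baseline outcome must be observed")
  obs <- which(!is.na(y))
  if (length(obs) == J) return(y)
  x <- as.numeric(x)
  mu_rand <- drop(crossprod(draw_rand$beta, x))
  mu_ref <- drop(crossprod(draw_ref$beta, x))
  n_last <- max(obs)
  inter <- setdiff(seq_len(n_last - 1L), obs)
  if (length(inter)) {
    cm <- conditional_moments(mu_rand, draw_rand$Sigma, obs, y[obs])
    # conditional_moments returns all missing indices; keep the
    # intermittent ones (pre-deviation gaps) from this MAR draw
    z <- draw_mvn(cm$mean, cm$cov)
    y[inter] <- z[match(inter, cm$miss_idx)]
  }
  post <- if (n_last < J) (n_last + 1L):J else integer(0)
  if (length(post)) {
    mu_star <- build_marginal_mean(method, mu_rand, mu_ref, n_last)
    sigma_star <- build_joint_covariance(method, draw_rand$Sigma,
                                         draw_ref$Sigma, n_last)
    pre <- seq_len(n_last)
    cm <- conditional_moments(mu_star, sigma_star, pre, y[pre])
    y[post] <- draw_mvn(cm$mean, cm$cov)
  }
  y
}
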