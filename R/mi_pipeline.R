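#' Default fixed-effect formula for the analysis model
#'
#' The analysis model is a random-intercept linear mixed model of the
#' outcome on treatment arm, visit month, their interaction,
#' time-varying treatment status (ART), its interaction with arm, and
#' baseline age:
#' `y ~ trt + month + trt:month + art + trt:art + age + (1 | id)`.
#'
#' @return a formula.
#' @export
lmm_formula <- function() {
  y ~ trt + month + trt:month + art + trt:art + age + (1 | id)
}

# Imputation-model design matrix for the whole trial: intercept plus
# requested baseline covariates. Columns constant across the trial are
# dropped, so both arms' coefficient matrices share one column layout.
imputation_design <- function(trial, covariates = c("age", "art")) {
  N <- n_patients(trial)
  X <- matrix(1, N, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    if ("age" %in% covariates && !all(is.na(trial$age)))
      X <- cbind(X, age = trial$age)
    if ("art" %in% covariates)
      X <- cbind(X, art = trial$art[, 1])
  }
  if (ncol(X) > 1) {
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(v) stats::var(v) > 0))
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Posterior parameter draws for every arm of a trial
#'
#' Runs one Gibbs data-augmentation chain per arm (on that arm's
#' outcomes and baseline covariates) and retains `K` thinned draws from
#' each, giving the `K` parameter sets used to create `K` imputed
#' datasets.
#'
#' @param trial a [longitudinal_trial].
#' @param K number of retained draws per arm.
#' @param covariates baseline covariates of the imputation model
#'   (subset of `c("age", "art")`; constant columns are dropped).
#' @param gibbs a [gibbs_config()]; its `rng_seed` is ignored in favour
#'   of `seed`.
#' @param seed integer master seed; each arm's chain gets a seed
#'   derived from it by a fixed counter scheme so any chain can be
#'   reproduced in isolation.
#' @return named list (one element per arm label) of lists of
#'   [mvn_params].
#' @export
posterior_draws <- function(trial, K, covariates = c("age", "art"),
                            gibbs = gibbs_config(), seed = 1L) {
  arms <- sort(unique(trial$arm))
  X <- imputation_design(trial, covariates)
  out <- vector("list", length(arms))
  names(out) <- as.character(arms)
  for (a in seq_along(arms)) {
    idx <- which(trial$arm == arms[a])
    Ya <- trial$Y[idx, , drop = FALSE]
    cfg <- gibbs_config(gibbs$burn_in, gibbs$thin,
                        rng_seed = derive_seed(seed, a))
    out[[a]] <- gibbs_posterior(Ya, X[idx, , drop = FALSE], cfg,
                                n_draws = K)
  }
  attr(out, "covariates") <- covariates
  out
}

# Deterministic 32-bit seed stream: seed -> k-th derived seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483629)
}

#' Complete a trial once from given parameter draws
#'
#' Applies [impute_patient()] to every incomplete patient, using the
#' `k`-th posterior draw of the patient's randomized arm and of the
#' reference arm. Patients in the reference arm (and all patients under
#' MAR) are imputed under randomized-arm MAR; LMCF uses each patient's
#' own arm.
#'
#' @param trial a [longitudinal_trial].
#' @param draws output of [posterior_draws()].
#' @param k which draw to use.
#' @param spec an [imputation_spec()].
#' @return a completed [longitudinal_trial] (mask all ones).
#' @export
apply_imputation <- function(trial, draws, k, spec) {
  covariates <- attr(draws, "covariates")
  X <- imputation_design(trial, covariates)
  Y <- trial$Y
  incomplete <- which(rowSums(trial$R) < n_visits(trial))
  for (i in incomplete) {
    a <- as.character(trial$arm[i])
    Xi <- X[i, ]
    method <- spec$method
    ref <- a
    if (method %in% c("J2R", "CDR", "CR")) {
      if (trial$arm[i] == spec$reference_arm) {
        method <- "MAR"        # reference-arm patients are MAR-imputed
      } else {
        ref <- as.character(spec$reference_arm)
      }
    }
    Y[i, ] <- impute_patient(trial$Y[i, ], Xi,
                             draw_rand = draws[[a]][[k]],
                             draw_ref = draws[[ref]][[k]],
                             method = method)
  }
  longitudinal_trial(Y, trial$arm, trial$visit_times, trial$age,
                     trial$art, trial$patient_id)
}

#' Create K multiply-imputed datasets
#'
#' Steps B--E of the pattern-mixture multiple-imputation workflow,
#' repeated `K` times: per-arm posterior draws via Gibbs data
#' augmentation, then one completed dataset per draw under the
#' specified post-deviation assumption. Observed cells are identical
#' across all `K` copies and the whole procedure is reproducible from
#' `seed`.
#'
#' @param trial a [longitudinal_trial].
#' @param spec an [imputation_spec()].
#' @param seed integer master seed.
#' @param covariates,gibbs passed to [posterior_draws()].
#' @return list of `K` completed [longitudinal_trial] objects.
#' @export
impute_k <- function(trial, spec, seed = 1L,
                     covariates = c("age", "art"),
                     gibbs = gibbs_config()) {
  if (spec$K < 1) stop("K must be >= 1")
  if (!any(trial$R == 0L))
    return(replicate(spec$K, trial, simplify = FALSE))
  draws <- posterior_draws(trial, spec$K, covariates, gibbs, seed)
  set.seed(derive_seed(seed, 1000L))
  lapply(seq_len(spec$K), function(k)
    apply_imputation(trial, draws, k, spec))
}

#' Fit the random-intercept linear mixed model
#'
#' REML fit (via `lme4::lmer`) of the analysis model to a trial in long
#' format. By default the full model of [lmm_formula()] is used; pass a
#' simpler formula (e.g. `y ~ trt * month + (1 | id)`) when covariates
#' are absent or constant.
#'
#' @param trial a [longitudinal_trial] or a long-format data.frame with
#'   columns `id`, `trt`, `month`, `y` (and `art`, `age` if the formula
#'   needs them). Missing outcomes are dropped (direct-likelihood
#'   analysis of the incomplete data).
#' @param formula mixed-model formula with a `(1 | id)` term.
#' @param REML logical; restricted maximum likelihood (default).
#' @param ... further arguments for [lme4::lmer()] (e.g. `control`).
#' @return object of class `lmm_fit`: `beta_hat` (named fixed
#'   effects), `cov_beta`, `sigma_b`, `sigma_e`, `converged`, `n_obs`,
#'   and the underlying `fit`.
#' @export
fit_lmm <- function(trial, formula = lmm_formula(), REML = TRUE, ...) {
  d <- if (inherits(trial, "longitudinal_trial")) as_long(trial) else trial
  d <- d[!is.na(d$y), , drop = FALSE]
  fixed <- lme4::nobars(formula)
  mm <- stats::model.matrix(fixed, d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- lme4::lmer(formula, data = d, REML = REML, ...)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    beta_hat = lme4::fixef(fit),
    cov_beta = as.matrix(stats::vcov(fit)),
    sigma_b = vc$sdcor[vc$grp == "id"],
    sigma_e = vc$sdcor[vc$grp == "Residual"],
    converged = converged,
    n_obs = nrow(d),
    fit = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit (random intercept, REML)\n")
  se <- sqrt(diag(x$cov_beta))
  print(data.frame(estimate = x$beta_hat, se = se,
                   row.names = names(x$beta_hat)))
  cat(sprintf("sigma_b = %.4g, sigma_e = %.4g, converged = %s\n",
              x$sigma_b, x$sigma_e, x$converged))
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines `K` per-imputation estimates and variances:
#' `q_bar = mean(estimates)`, within-imputation variance `W = mean
#' (variances)`, between-imputation variance `B = var(estimates)`,
#' total variance `T = W + (1 + 1/K) B`, degrees of freedom
#' `df = (K - 1) (1 + W / ((1 + 1/K) B))^2` (infinite when `B = 0`),
#' and a two-sided Wald p-value from the t distribution on `df`.
#' The small-sample (Barnard--Rubin) degrees of freedom are available
#' via `df_complete`.
#'
#' @param estimates numeric vector of K point estimates.
#' @param variances numeric vector of K squared standard errors.
#' @param df_complete optional complete-data degrees of freedom; when
#'   supplied, the Barnard--Rubin adjusted df are returned instead of
#'   the classic Rubin df.
#' @return object of class `pooled_estimate`: `q_bar`, `W`, `B`, `T`,
#'   `se`, `df`, `p_value`, `K`.
#' @export
pool_rubin <- function(estimates, variances, df_complete = NULL) {
  K <- length(estimates)
  if (K < 2) stop("need K >= 2 estimates to pool")
  if (length(variances) != K) stop("estimates and variances differ in length")
  if (any(variances <= 0)) stop("variances must be positive")
  q_bar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  T_var <- W + (1 + 1 / K) * B
  if (B > 0) {
    r <- (1 + 1 / K) * B / W
    df <- (K - 1) * (1 + 1 / r)^2
    if (!is.null(df_complete)) {
      lambda <- (1 + 1 / K) * B / T_var
      df_obs <- (df_complete + 1) / (df_complete + 3) *
        df_complete * (1 - lambda)
      df <- 1 / (1 / df + 1 / df_obs)
    }
  } else {
    df <- Inf
  }
  se <- sqrt(T_var)
  p <- 2 * stats::pt(abs(q_bar) / se, df = df, lower.tail = FALSE)
  structure(list(q_bar = q_bar, W = W, B = B, T = T_var, se = se,
                 df = df, p_value = p, K = K),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "pooled_estimate: %.4g (se %.4g, df %.3g, p %.3g) from K = %d\n",
    x$q_bar, x$se, x$df, x$p_value, x$K))
  invisible(x)
}

# Fit + pool one imputation method over completed datasets; returns a
# data.frame of pooled coefficients.
pool_fits <- function(completed, formula, df_complete = NULL) {
  fits <- lapply(completed, fit_lmm, formula = formula)
  coefs <- names(fits[[1]]$beta_hat)
  do.call(rbind, lapply(coefs, function(cf) {
    est <- vapply(fits, function(f) f$beta_hat[[cf]], 0)
    v <- vapply(fits, function(f) f$cov_beta[cf, cf], 0)
    p <- pool_rubin(est, v, df_complete = df_complete)
    data.frame(coefficient = cf, estimate = p$q_bar, se = p$se,
               df = p$df, p = p$p_value, W = p$W, B = p$B, T = p$T)
  }))
}

#' De jure / de facto sensitivity analysis
#'
#' Runs the full pattern-mixture multiple-imputation sensitivity
#' analysis: for each requested method, create `K` imputed datasets,
#' fit the analysis model to each, pool with Rubin's rules, and report
#' every fixed-effect coefficient. The reference-based methods (J2R,
#' CDR, CR) are run once per requested reference arm; with
#' `reference = "both"` they each contribute two rows per coefficient,
#' labelled `(P-)` for the control-arm reference and `(P+)` for the
#' active-arm reference.
#'
#' @param trial a [longitudinal_trial].
#' @param methods character vector among
#'   `c("MAR", "LMCF", "J2R", "CDR", "CR")`.
#' @param reference `"both"`, or an arm label used for all
#'   reference-based methods.
#' @param K imputations per method.
#' @param seed master seed.
#' @param formula analysis-model formula (default [lmm_formula()]).
#' @param covariates,gibbs imputation-model settings, see
#'   [posterior_draws()].
#' @return data.frame with columns `analysis`, `method`, `reference`,
#'   `coefficient`, `estimate`, `se`, `df`, `p`.
#' @export
sensitivity_analysis <- function(trial,
                                 methods = c("MAR", "LMCF", "J2R",
                                             "CDR", "CR"),
                                 reference = "both", K = 50, seed = 1L,
                                 formula = lmm_formula(),
                                 covariates = c("age", "art"),
                                 gibbs = gibbs_config()) {
  methods <- match.arg(toupper(methods), IMPUTE_METHODS,
                       several.ok = TRUE)
  arms <- sort(unique(trial$arm))
  rows <- list()
  any_missing <- any(trial$R == 0L)
  draws <- if (any_missing)
    posterior_draws(trial, K, covariates, gibbs, seed) else NULL
  for (m in methods) {
    refs <- if (m %in% c("J2R", "CDR", "CR")) {
      if (identical(reference, "both")) arms else as.integer(reference)
    } else NA_integer_
    for (r in refs) {
      spec <- imputation_spec(m, if (is.na(r)) NULL else r, K)
      if (any_missing) {
        set.seed(derive_seed(seed, 2000L + match(m, IMPUTE_METHODS)))
        completed <- lapply(seq_len(K), function(k)
          apply_imputation(trial, draws, k, spec))
        res <- pool_fits(completed, formula)
      } else {
        f <- fit_lmm(trial, formula)
        se <- sqrt(diag(f$cov_beta))
        res <- data.frame(coefficient = names(f$beta_hat),
                          estimate = unname(f$beta_hat), se = se,
                          df = Inf,
                          p = 2 * stats::pnorm(abs(f$beta_hat) / se,
                                               lower.tail = FALSE),
                          W = se^2, B = 0, T = se^2)
      }
      lab <- if (is.na(r)) m else
        sprintf("%s (%s)", m, if (r == min(arms)) "P-" else "P+")
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(analysis = lab, method = m, reference = r),
              res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
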