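#' Simulation-study configuration
#'
#' Describes one simulation experiment: replicate trials are generated
#' from [generative_params()], missingness is imposed with a calibrated
#' dropout model for every mechanism x rate cell, and each requested
#' method is evaluated by bias, RMSE and coverage of the nominal 95%
#' interval for the treatment, time and treatment-by-time coefficients.
#'
#' `"ML"` is the direct-likelihood analysis (random-intercept mixed
#' model fitted to the incomplete data); the remaining methods are
#' multiple-imputation methods pooled with Rubin's rules. Reference-
#' based methods use the control arm (arm 0) as reference, the usual
#' conservative choice for an active-vs-placebo comparison.
#'
#' @param n_reps replicate trials per cell.
#' @param n_patients patients per replicate.
#' @param mechanisms subset of `c("MCAR", "MAR")`.
#' @param rates target overall dropout (non-completion) fractions.
#' @param methods subset of `c("ML", "MAR", "LMCF", "J2R", "CDR",
#'   "CR")`.
#' @param K imputations per MI method.
#' @param master_seed integer master seed; every cell and replicate
#'   derives its own seed from it.
#' @param params generative parameters.
#' @param mar_slope logit slope of the MAR dropout model.
#' @param gibbs [gibbs_config()] for the imputation chains. The
#'   default here is shorter than the engine default (burn-in 100,
#'   thinning 25): the per-arm chains in this setting mix quickly and
#'   the study runs thousands of them.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_reps = 250, n_patients = 200,
                       mechanisms = "MCAR", rates = 0.05,
                       methods = c("ML", "MAR"), K = 10,
                       master_seed = 1L,
                       params = generative_params(),
                       mar_slope = 0.5,
                       gibbs = gibbs_config(burn_in = 100, thin = 25)) {
  stopifnot(n_reps >= 1, all(rates >= 0 & rates < 1))
  mechanisms <- match.arg(toupper(mechanisms), c("MCAR", "MAR"),
                          several.ok = TRUE)
  methods <- match.arg(toupper(methods),
                       c("ML", IMPUTE_METHODS), several.ok = TRUE)
  structure(list(n_reps = as.integer(n_reps),
                 n_patients = as.integer(n_patients),
                 mechanisms = mechanisms, rates = rates,
                 methods = methods, K = as.integer(K),
                 master_seed = as.integer(master_seed),
                 params = params, mar_slope = mar_slope,
                 gibbs = gibbs),
            class = "sim_config")
}

#' Bias, RMSE and coverage of a set of replicate estimates
#'
#' Standard simulation metrics: `bias = mean(est) - truth`,
#' `rmse = sqrt(mean((est - truth)^2))`, and `coverage` the fraction
#' of nominal 95% intervals `est +/- t(df, 0.975) * se` containing the
#' truth (`df = Inf` gives Wald/normal intervals). Monte-Carlo
#' standard errors accompany each metric.
#'
#' @param estimates per-replicate point estimates.
#' @param ses per-replicate standard errors (> 0).
#' @param dfs per-replicate degrees of freedom (recycled; use `Inf`
#'   for likelihood fits).
#' @param truth true parameter value.
#' @return list with `bias`, `rmse`, `coverage`, `mc_se_bias`,
#'   `mc_se_coverage`, `n`.
#' @export
metrics <- function(estimates, ses, dfs = Inf, truth) {
  n <- length(estimates)
  if (n == 0) stop("no estimates supplied")
  if (length(ses) != n) stop("estimates and ses differ in length")
  if (any(ses <= 0)) stop("ses must be positive")
  dfs <- rep_len(dfs, n)
  err <- estimates - truth
  tcrit <- stats::qt(0.975, df = dfs)
  cover <- abs(err) <= tcrit * ses
  cv <- mean(cover)
  list(bias = mean(err),
       rmse = sqrt(mean(err^2)),
       coverage = cv,
       mc_se_bias = stats::sd(err) / sqrt(n),
       mc_se_coverage = sqrt(cv * (1 - cv) / n),
       n = n)
}

# Coefficient names of the simulation analysis model, mapped to the
# generative betas they estimate.
STUDY_COEFS <- c(treatment = "trt", time = "month",
                 `treatment:time` = "trt:month")

#' Run a simulation study
#'
#' For every mechanism x rate cell: calibrate the dropout intercept,
#' then for each replicate generate a complete trial, impose dropout,
#' and analyse it with every requested method -- `"ML"` fits the
#' random-intercept model `y ~ trt * month + (1 | id)` directly to the
#' observed rows; each MI method imputes `K` completed datasets
#' (sharing one set of posterior draws per replicate across methods),
#' fits the same model to each, and pools with Rubin's rules. Metrics
#' are reported per (mechanism, rate, method, coefficient). Replicates
#' whose analysis fails are logged and excluded with a count.
#'
#' @param config a [sim_config()].
#' @param verbose print per-cell progress (default `FALSE`).
#' @return data.frame of class `metrics_table` with columns
#'   `mechanism`, `rate`, `method`, `coefficient`, `bias`, `rmse`,
#'   `coverage`, `mc_se_bias`, `mc_se_coverage`, `n_reps`, plus an
#'   attribute `failures` counting excluded replicates per cell.
#' @export
run_study <- function(config = sim_config(), verbose = FALSE) {
  truth <- config$params$beta[2:4]
  names(truth) <- names(STUDY_COEFS)
  form <- y ~ trt * month + (1 | id)
  mi_methods <- setdiff(config$methods, "ML")
  rows <- list()
  failures <- list()
  for (mech in config$mechanisms) {
    for (rate in config$rates) {
      model <- dropout_model(mech,
                             slope = if (mech == "MAR")
                               config$mar_slope else 0)
      cell_id <- paste(mech, rate)
      if (rate > 0) {
        model$intercept <- calibrate_rate(
          rate, model, config$params,
          seed = derive_seed(config$master_seed, 77L))
      } else {
        model$intercept <- -Inf
      }
      res <- vector("list", config$n_reps)
      nfail <- 0L
      for (r in seq_len(config$n_reps)) {
        seed_r <- derive_seed(config$master_seed,
                              r + 100000L * match(mech, c("MCAR", "MAR")) +
                                1000000L * round(rate * 100))
        res[[r]] <- tryCatch(
          run_replicate(config, model, rate, seed_r, form, mi_methods),
          error = function(e) {
            message("replicate ", r, " in cell [", cell_id,
                    "] failed: ", conditionMessage(e))
            NULL
          })
        if (is.null(res[[r]])) nfail <- nfail + 1L
      }
      failures[[cell_id]] <- nfail
      res <- res[!vapply(res, is.null, TRUE)]
      for (m in config$methods) {
        for (cf in names(STUDY_COEFS)) {
          est <- vapply(res, function(x) x[[m]][cf, "estimate"], 0)
          se <- vapply(res, function(x) x[[m]][cf, "se"], 0)
          df <- vapply(res, function(x) x[[m]][cf, "df"], 0)
          mt <- metrics(est, se, df, truth[[cf]])
          rows[[length(rows) + 1L]] <- data.frame(
            mechanism = mech, rate = rate, method = m,
            coefficient = cf, bias = mt$bias, rmse = mt$rmse,
            coverage = mt$coverage, mc_se_bias = mt$mc_se_bias,
            mc_se_coverage = mt$mc_se_coverage, n_reps = mt$n)
        }
      }
      if (verbose)
        message("cell [", cell_id, "]: done (", nfail, " failures)")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  class(out) <- c("metrics_table", class(out))
  out
}

# One replicate: generate, impose dropout, analyse with every method.
# Returns a list (per method) of coefficient matrices with rows
# treatment/time/treatment:time and columns estimate/se/df.
run_replicate <- function(config, model, rate, seed, form, mi_methods) {
  trial <- generate_trial(config$params, config$n_patients,
                          seed = seed)
  if (rate > 0) trial <- impose_dropout(trial, model)
  out <- list()
  extract <- function(fit) {
    se <- sqrt(diag(fit$cov_beta))
    m <- cbind(estimate = fit$beta_hat[STUDY_COEFS],
               se = se[STUDY_COEFS], df = Inf)
    rownames(m) <- names(STUDY_COEFS)
    m
  }
  if ("ML" %in% config$methods)
    out$ML <- extract(fit_lmm(trial, form))
  if (length(mi_methods)) {
    if (any(trial$R == 0L)) {
      draws <- posterior_draws(trial, config$K, covariates = NULL,
                               gibbs = config$gibbs,
                               seed = derive_seed(seed, 3L))
      for (m in mi_methods) {
        spec <- imputation_spec(m, reference_arm = if (m %in%
          c("J2R", "CDR", "CR")) 0L else NULL, K = config$K)
        set.seed(derive_seed(seed, 13L + match(m, IMPUTE_METHODS)))
        completed <- lapply(seq_len(config$K), function(k)
          apply_imputation(trial, draws, k, spec))
        pooled <- pool_fits(completed, form)
        m2 <- as.matrix(pooled[match(STUDY_COEFS,
                                     pooled$coefficient),
                               c("estimate", "se", "df")])
        rownames(m2) <- names(STUDY_COEFS)
        out[[m]] <- m2
      }
    } else {
      cfit <- extract(fit_lmm(trial, form))
      for (m in mi_methods) out[[m]] <- cfit
    }
  }
  out
}
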