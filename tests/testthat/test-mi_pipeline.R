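test_that("impute_k copies complete trials verbatim and is reproducible", {
  tr <- toy_trial(n = 30)
  sp <- imputation_spec("MAR", K = 3)
  out <- impute_k(tr, sp, seed = 1)
  expect_length(out, 3)
  for (k in 1:3) expect_identical(out[[k]]$Y, tr$Y)

  trm <- impose_dropout(toy_trial(n = 60),
                        dropout_model("MCAR", intercept = -2),
                        seed = 2)
  a <- impute_k(trm, sp, seed = 9, gibbs = fast_gibbs())
  b <- impute_k(trm, sp, seed = 9, gibbs = fast_gibbs())
  expect_identical(a, b)
  # observed cells identical across imputations, missing cells vary
  obs <- trm$R == 1L
  expect_identical(a[[1]]$Y[obs], trm$Y[obs])
  expect_identical(a[[2]]$Y[obs], trm$Y[obs])
  expect_false(identical(a[[1]]$Y[!obs], a[[2]]$Y[!obs]))
})

test_that("MAR imputation recovers the generating means of imputed cells", {
  params <- generative_params(sigma_b = 2, sigma_e = 1)
  tr <- generate_trial(params, 300, seed = 3)
  trm <- impose_dropout(tr, dropout_model("MCAR", intercept = -1.2),
                        seed = 4)
  out <- impute_k(trm, imputation_spec("MAR", K = 50), seed = 5,
                  covariates = NULL, gibbs = gibbs_config(50, 5))
  miss <- trm$R == 0L
  truth <- outer(tr$arm, params$visit_times, function(a, t)
    params$beta[1] + params$beta[2] * a + params$beta[3] * t +
      params$beta[4] * a * t)
  imp <- sapply(out, function(x) mean(x$Y[miss] - truth[miss]))
  # MC se over patients-cells, inflated by between-imputation spread
  cell_sd <- sd(out[[1]]$Y[miss] - truth[miss])
  mc_se <- cell_sd / sqrt(sum(miss))
  expect_lt(abs(mean(imp)), 3 * mc_se)
})

test_that("fit_lmm recovers coefficients in the noiseless limit", {
  params <- generative_params(beta = c(13, 0.75, 0.11, -0.19),
                              sigma_b = 0, sigma_e = 1e-6)
  tr <- generate_trial(params, 40, seed = 6)
  f <- fit_lmm(tr, y ~ trt * month + (1 | id))
  expect_equal(unname(f$beta_hat),
               c(13, 0.75, 0.11, -0.19), tolerance = 1e-4)
})

test_that("cross-sectional reduction returns the difference of arm means", {
  set.seed(7)
  n <- 40
  d <- data.frame(id = 1:n, trt = rep(0:1, n / 2),
                  month = 0, y = rnorm(n, 10))
  f <- fit_lmm(d, y ~ trt + (1 | id),
               control = lme4::lmerControl(
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore"))
  diff_means <- mean(d$y[d$trt == 1]) - mean(d$y[d$trt == 0])
  expect_equal(unname(f$beta_hat["trt"]), diff_means,
               tolerance = 1e-6)
})

test_that("fit_lmm recovers variance components from simulated data", {
  params <- generative_params(sigma_b = 2, sigma_e = 1)
  tr <- generate_trial(params, 500, seed = 8)
  f <- fit_lmm(tr, y ~ trt * month + (1 | id))
  expect_lt(abs(f$sigma_b - 2) / 2, 0.15)
  expect_lt(abs(f$sigma_e - 1) / 1, 0.15)
  expect_true(f$converged)
})

test_that("fit_lmm names aliased columns of a singular design", {
  tr <- toy_trial(n = 20)
  d <- as_long(tr)
  d$dup <- d$month
  expect_error(fit_lmm(d, y ~ month + dup + (1 | id)), "dup")
})

test_that("Rubin pooling follows the combining rules", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$q_bar, 2)
  expect_equal(p$W, 1)
  expect_equal(p$B, 2)
  expect_equal(p$T, 4)
  expect_equal(p$df, (1 + 1 / 3)^2)

  # identical estimates: no between-imputation variance
  p0 <- pool_rubin(rep(1.5, 4), rep(0.25, 4))
  expect_equal(p0$B, 0)
  expect_equal(p0$T, p0$W)
  expect_identical(p0$df, Inf)

  expect_error(pool_rubin(1, 1), "K >= 2")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "positive")

  # Rubin identity on random pooled outputs
  set.seed(9)
  for (i in 1:20) {
    K <- sample(2:10, 1)
    est <- rnorm(K); v <- rexp(K) + 0.1
    p <- pool_rubin(est, v)
    expect_equal(p$T, p$W + (1 + 1 / K) * p$B, tolerance = 1e-12)
    expect_gte(p$T, p$W)
    if (p$B > 0) expect_gt(p$df, 0)
  }
})

test_that("Barnard-Rubin df are smaller than classic Rubin df", {
  p1 <- pool_rubin(c(1, 1.2, 0.8), c(1, 1, 1))
  p2 <- pool_rubin(c(1, 1.2, 0.8), c(1, 1, 1), df_complete = 50)
  expect_lt(p2$df, p1$df)
  expect_lt(p2$df, 50 + 1)
})

test_that("sensitivity analysis on a complete trial equals the single mixed-model fit", {
  tr <- toy_trial(n = 40)
  res <- sensitivity_analysis(tr, K = 3, seed = 1)
  f <- fit_lmm(tr)
  for (an in unique(res$analysis)) {
    sub <- res[res$analysis == an, ]
    expect_equal(sub$estimate, unname(f$beta_hat), tolerance = 1e-12)
    expect_equal(sub$B, rep(0, nrow(sub)))
  }
  # row count: MAR + LMCF once, J2R/CDR/CR twice (both references)
  expect_identical(length(unique(res$analysis)), 8L)
})

test_that("all methods agree within Monte-Carlo error on MAR-generated data", {
  params <- generative_params(sigma_b = 2, sigma_e = 1)
  tr <- generate_trial(params, 300, seed = 11)
  trm <- impose_dropout(tr, dropout_model("MCAR", intercept = -1.8),
                        seed = 12)
  res <- sensitivity_analysis(trm, reference = 0, K = 10, seed = 13,
                              formula = y ~ trt * month + (1 | id),
                              covariates = NULL,
                              gibbs = fast_gibbs())
  trt <- res[res$coefficient == "trt", ]
  spread <- max(trt$estimate) - min(trt$estimate)
  expect_lt(spread, 3 * max(trt$se))
  expect_identical(nrow(trt), 5L)
})
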