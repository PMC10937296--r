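test_that("with no random effects the engine is exactly logistic regression", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  tot <- rpois(n, 30) + 1
  m <- rbinom(n, tot, plogis(0.2 + 0.5 * x))
  f <- fit_binomial_glmm(m, tot, data.frame(x = x), fixed = ~ x,
                         random = character(0))
  g <- glm(cbind(m, tot - m) ~ x, family = binomial)
  expect_lt(max(abs(f$beta - coef(g))), 1e-6)
  expect_lt(abs(f$loglik - as.numeric(logLik(g))), 1e-6)
  expect_lt(max(abs(f$vcov_beta - vcov(g))), 1e-6)
})

test_that("the Laplace fit agrees with an independent mixed-model fit", {
  set.seed(21)
  toy <- make_glmm_toy(coverage_mean = 40)
  f <- fit_binomial_glmm(toy$m, toy$tot, toy$data, fixed = ~ x,
                         random = "grp")
  g <- suppressMessages(lme4::glmer(
    cbind(toy$m, toy$tot - toy$m) ~ x + (1 | grp),
    data = toy$data, family = binomial))
  expect_lt(abs(f$loglik - as.numeric(logLik(g))), 5e-3)
  expect_lt(max(abs(f$beta - lme4::fixef(g))), 2e-2)
  expect_lt(abs(f$sd_components[[1]] -
                  sqrt(as.data.frame(lme4::VarCorr(g))$vcov[1])), 3e-2)
})

test_that("Laplace log-likelihood matches adaptive quadrature on a deep toy", {
  set.seed(5)
  for (i in 1:3) {
    toy <- make_glmm_toy(coverage_mean = 2000)
    f <- fit_binomial_glmm(toy$m, toy$tot, toy$data, fixed = ~ x,
                           random = "grp")
    eta <- drop(model.matrix(~ x, toy$data) %*% f$beta)
    ll <- agq_loglik(toy$m, toy$tot, eta, toy$grp, f$sd_components[[1]])
    expect_lt(abs(f$loglik - ll), 1e-3)
  }
})

test_that("duplicating every row leaves the coefficient estimates unchanged", {
  # sufficiency of the binomial likelihood: doubling every row rescales the
  # log-likelihood but cannot move the fixed-effect optimum
  set.seed(11)
  toy <- make_glmm_toy(coverage_mean = 30)
  f1 <- fit_binomial_glmm(toy$m, toy$tot, toy$data, fixed = ~ x,
                          random = character(0))
  idx <- rep(seq_along(toy$m), 2)
  f2 <- fit_binomial_glmm(toy$m[idx], toy$tot[idx], toy$data[idx, ],
                          fixed = ~ x, random = character(0))
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-6)
  expect_lt(abs(2 * f1$loglik - f2$loglik), 1e-6)
})

test_that("refitting from the optimum is stationary", {
  set.seed(13)
  toy <- make_glmm_toy(coverage_mean = 50)
  f1 <- fit_binomial_glmm(toy$m, toy$tot, toy$data, fixed = ~ x,
                          random = "grp")
  f2 <- fit_binomial_glmm(toy$m, toy$tot, toy$data, fixed = ~ x,
                          random = "grp")
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
})

test_that("likelihood ratio tests follow their closed form", {
  mkfit <- function(ll, npar, nms) {
    structure(list(loglik = ll, n_par = npar, n_obs = 50,
                   beta = setNames(rep(0, npar), nms),
                   random = "g"), class = "bin_glmm")
  }
  f0 <- mkfit(-100, 2, c("(Intercept)", "treatment"))
  f1 <- mkfit(-97.5, 4, c("(Intercept)", "treatment", "days",
                          "treatment:days"))
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$statistic, 5)
  expect_equal(lrt$df, 2)
  expect_equal(lrt$p_value, exp(-2.5), tolerance = 1e-10)

  # identical models: statistic 0, p 1 (via a tiny negative clamp)
  lrtid <- likelihood_ratio_test(mkfit(-100, 2, c("(Intercept)", "t")),
                                 mkfit(-100 - 1e-8, 3,
                                       c("(Intercept)", "t", "d")))
  expect_equal(lrtid$statistic, 0)
  expect_equal(lrtid$p_value, 1)

  expect_error(likelihood_ratio_test(f1, f0), "nested|add")
  f0b <- mkfit(-100, 2, c("(Intercept)", "other"))
  expect_error(likelihood_ratio_test(f0b, f1), "nested")
})

test_that("slope contrasts combine coefficients per treatment", {
  fit <- structure(list(
    beta = c("(Intercept)" = -1, "treatmentenlarged" = 0.5,
             "days_since_fledging" = 0.10,
             "treatmentenlarged:days_since_fledging" = 0.11),
    vcov_beta = diag(4e-4, 4), n_par = 4, n_obs = 50,
    xlevels = list(treatment = c("reduced", "enlarged"))),
    class = "bin_glmm")
  dimnames(fit$vcov_beta) <- list(names(fit$beta), names(fit$beta))
  sc <- slope_contrasts(fit, "days_since_fledging", "treatment")
  expect_equal(sc$slope[sc$group == "reduced"], 0.10)
  expect_equal(sc$slope[sc$group == "enlarged"], 0.21)
  expect_equal(sc$se[sc$group == "reduced"], 0.02)
  expect_equal(sc$se[sc$group == "enlarged"], sqrt(8e-4))

  scb <- slope_contrasts(fit, "days_since_fledging", "treatment",
                         adjust = "bonferroni")
  expect_equal(scb$p_adjusted, pmin(1, 2 * scb$p_raw))

  # no interaction term: both groups share the slope
  fit2 <- fit
  fit2$beta <- fit$beta[1:3]
  fit2$vcov_beta <- fit$vcov_beta[1:3, 1:3]
  sc2 <- slope_contrasts(fit2, "days_since_fledging", "treatment")
  expect_equal(sc2$slope[1], sc2$slope[2])

  expect_error(slope_contrasts(fit, "nonexistent"), "not in the model")
})

test_that("Pearson dispersion behaves under the generative extremes", {
  set.seed(17)
  # binomial truth, no random effects: dispersion near 1 on average
  disp <- vapply(1:60, function(i) {
    n <- 80
    x <- rnorm(n)
    tot <- rpois(n, 30) + 1
    m <- rbinom(n, tot, plogis(0.3 * x))
    pearson_dispersion(fit_binomial_glmm(m, tot, data.frame(x = x),
                                         fixed = ~ x, random = character(0)))
  }, 0)
  expect_lt(abs(mean(disp) - 1), 0.1)

  # beta-binomial (extra-variance) data: dispersion above 1
  disp2 <- vapply(1:30, function(i) {
    n <- 80
    x <- rnorm(n)
    tot <- rpois(n, 30) + 1
    p <- plogis(0.3 * x + rnorm(n, 0, 0.6))
    m <- rbinom(n, tot, p)
    pearson_dispersion(fit_binomial_glmm(m, tot, data.frame(x = x),
                                         fixed = ~ x, random = character(0)))
  }, 0)
  expect_gt(mean(disp2), 1.5)
})

test_that("degenerate responses are flagged, never silently fitted", {
  n <- 20
  d <- data.frame(x = rnorm(n))
  expect_warning(f <- fit_binomial_glmm(rep(0L, n), rep(10L, n), d,
                                        fixed = ~ x, random = character(0)),
                 "separation")
  expect_true(f$separation)
  expect_error(fit_binomial_glmm(rep(5L, n), rep(4L, n), d, fixed = ~ x),
               "meth <= total")
  expect_error(fit_binomial_glmm(rep(0L, n), rep(0L, n), d, fixed = ~ x),
               ">= 1")
  # aliased fixed effects are named
  d2 <- data.frame(x = rnorm(n))
  d2$y <- d2$x
  expect_error(fit_binomial_glmm(rep(2L, n), rep(10L, n), d2,
                                 fixed = ~ x + y, random = character(0)),
               "aliased")
})
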