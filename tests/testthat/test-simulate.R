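test_that("brood sizes follow the manipulation arithmetic", {
  cfg <- sim_config(n_cf_pairs = 16, base_brood_size = 9, manipulation = 3,
                    n_sites = 10, category_plan = NULL)
  des <- simulate_design(cfg)
  sizes <- table(des$brood_rearing, des$treatment)
  enl <- sizes[, "enlarged"][sizes[, "enlarged"] > 0]
  red <- sizes[, "reduced"][sizes[, "reduced"] > 0]
  expect_true(all(enl == 12))
  expect_true(all(red == 6))
  expect_equal(length(enl), 16)
  expect_equal(length(red), 16)

  cfg0 <- sim_config(manipulation = 0, n_sites = 10, category_plan = NULL)
  des0 <- simulate_design(cfg0)
  sz <- table(des0$brood_rearing)
  expect_true(all(sz == cfg0$base_brood_size))
})

test_that("realized recapture fractions match the treatment probabilities", {
  hits <- c(reduced = 0, enlarged = 0)
  n <- c(reduced = 0, enlarged = 0)
  for (s in 1:40) {
    des <- simulate_design(sim_config(seed = s, n_sites = 1,
                                      category_plan = NULL))
    for (tr in c("reduced", "enlarged")) {
      sel <- des$treatment == tr
      hits[tr] <- hits[tr] + sum(des$recaptured[sel])
      n[tr] <- n[tr] + sum(sel)
    }
  }
  # binomial error around the configured probabilities
  for (tr in c("reduced", "enlarged")) {
    p <- if (tr == "reduced") 0.3051 else 0.1643
    se <- sqrt(p * (1 - p) / n[tr])
    expect_lt(abs(hits[tr] / n[tr] - p), 4 * se)
  }
})

test_that("design structure and failure modes are as declared", {
  cfg <- sim_config(n_sites = 5, category_plan = NULL, seed = 2)
  des <- simulate_design(cfg)
  expect_true(all(des$days_since_fledging[des$recaptured] >=
                    cfg$days_range[1]))
  expect_true(all(des$days_since_fledging[des$recaptured] <=
                    cfg$days_range[2]))
  expect_equal(des$test_date[des$recaptured],
               des$fledge_date[des$recaptured] +
                 des$days_since_fledging[des$recaptured])
  # every individual carries both broods within its own CF pair
  expect_true(all(startsWith(des$brood_origin, des$cf_pair)))
  expect_true(all(startsWith(des$brood_rearing, des$cf_pair)))
  # zero recapture in one treatment is an explicit error naming it
  bad <- sim_config(recapture_prob_enlarged = 0, n_sites = 5,
                    category_plan = NULL)
  expect_error(simulate_design(bad), "enlarged")
})

test_that("simulated counts respect the binomial bounds and determinism", {
  cfg <- sim_config(n_sites = 50, category_plan = NULL, seed = 4)
  des <- simulate_design(cfg)
  a <- simulate_methylation(des, cfg)
  b <- simulate_methylation(des, cfg)
  expect_identical(a$matrix$meth, b$matrix$meth)
  expect_identical(a$matrix$total, b$matrix$total)
  expect_true(all(a$matrix$meth <= a$matrix$total, na.rm = TRUE))
  expect_true(all(a$matrix$meth >= 0, na.rm = TRUE))
  expect_true(all(a$truth$slope_enlarged == 0))
  expect_error(simulate_methylation(des, sim_config(n_sites = 0)),
               "nothing to simulate|exceed")
})

test_that("planted slopes move mean methylation in the planted direction", {
  plan <- data.frame(category = "opposing_enlarged_up", n = 30,
                     slope_enlarged = 0.02, slope_reduced = -0.02)
  cfg <- sim_config(n_sites = 30, category_plan = plan, seed = 6,
                    re_sd_origin = 0, re_sd_rearing = 0,
                    baseline_logit_mix = list(weights = 1, means = 0, sds = 0.1))
  des <- simulate_design(cfg)
  sim <- simulate_methylation(des, cfg)
  d <- des[des$recaptured, ]
  frac <- sim$matrix$meth / sim$matrix$total
  # correlation of methylation fraction with days, averaged across sites
  for (tr in c("enlarged", "reduced")) {
    sel <- d$treatment == tr
    r <- apply(frac[, sel], 1, function(f)
      cor(f, d$days_since_fledging[sel], use = "complete.obs"))
    if (tr == "enlarged") expect_gt(mean(r), 0.2) else expect_lt(mean(r), -0.2)
  }
})

test_that("null counts are binomial: per-site dispersion near 1", {
  cfg <- sim_config(n_sites = 150, category_plan = NULL, seed = 8,
                    re_sd_origin = 0, re_sd_rearing = 0,
                    obs_overdispersion_sd = 0,
                    baseline_logit_mix = list(weights = 1, means = 0, sds = 0.5))
  des <- simulate_design(cfg)
  sim <- simulate_methylation(des, cfg)
  d <- des[des$recaptured, ]
  disp <- vapply(seq_len(150), function(s) {
    tt <- sim$matrix$total[s, ]
    ok <- !is.na(tt) & tt > 0
    m <- sim$matrix$meth[s, ok]; tt <- tt[ok]
    p <- sum(m) / sum(tt)
    if (p <= 0 || p >= 1) return(NA_real_)
    sum((m - tt * p)^2 / (tt * p * (1 - p))) / (length(m) - 1)
  }, 0)
  expect_lt(abs(mean(disp, na.rm = TRUE) - 1), 0.1)
})

test_that("stronger planted slopes give monotonically larger recovered slopes", {
  slopes <- c(0.005, 0.015, 0.03)
  rec <- vapply(slopes, function(sl) {
    plan <- data.frame(category = "enlarged_only_up", n = 25,
                       slope_enlarged = sl, slope_reduced = 0)
    cfg <- sim_config(n_sites = 25, category_plan = plan, seed = 10,
                      baseline_logit_mix = list(weights = 1, means = 0,
                                                sds = 0.2))
    des <- simulate_design(cfg)
    sim <- simulate_methylation(des, cfg)
    d <- des[des$recaptured, ]
    sel <- d$treatment == "enlarged"
    est <- vapply(seq_len(25), function(s) {
      m <- sim$matrix$meth[s, sel]; tt <- sim$matrix$total[s, sel]
      ok <- !is.na(tt) & tt > 0
      coef(glm(cbind(m[ok], tt[ok] - m[ok]) ~ d$days_since_fledging[sel][ok],
               family = binomial))[2]
    }, 0)
    mean(est)
  }, 0)
  expect_true(all(diff(rec) > 0))
})

test_that("phenotypes are exact linear predictors when noise is removed", {
  cfg <- sim_config(n_sites = 1, category_plan = NULL, seed = 3)
  des <- simulate_design(cfg)
  pp <- phenotype_params(w14_sigma = 0, wpost_sigma = 0, p3_sigma = 0,
                         expl_sigma = 0, re_sd_origin = 0, re_sd_rearing = 0)
  ph <- simulate_phenotypes(des, pp, seed = 3)
  enl <- as.numeric(ph$treatment == "enlarged")
  expect_equal(ph$exploration_score,
               pp$expl_intercept +
                 (pp$expl_days_reduced * (1 - enl) +
                    pp$expl_days_enlarged * enl) * ph$days_since_fledging)
  expect_equal(ph$delta_weight, ph$weight_post - ph$weight_day14)
  expect_error(simulate_phenotypes(des, phenotype_params(expl_sigma = NA)),
               "finite")
})

test_that("null phenotype slopes are centred on zero across seeds", {
  pp <- phenotype_params(expl_days_reduced = 0, expl_days_enlarged = 0,
                         expl_sigma = 1, re_sd_origin = 0, re_sd_rearing = 0)
  sl <- vapply(1:40, function(s) {
    des <- simulate_design(sim_config(seed = s, n_sites = 1,
                                      category_plan = NULL))
    ph <- simulate_phenotypes(des, pp, seed = s)
    coef(lm(exploration_score ~ days_since_fledging, ph))[2]
  }, 0)
  expect_lt(abs(mean(sl)), 2 * sd(sl) / sqrt(length(sl)) + 0.005)
})
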