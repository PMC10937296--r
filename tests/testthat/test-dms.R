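test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(23)
  for (i in 1:10) {
    p <- runif(sample(5:80, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  # NA p-values propagate and are excluded from the number of tests
  p <- c(0.01, NA, 0.02, NaN, 0.03)
  q <- bh_adjust(p)
  expect_true(all(is.na(q[c(2, 4)])))
  expect_equal(q[!is.na(q)], bh_bruteforce(c(0.01, 0.02, 0.03)))
  # widened universe scales the q-values up
  expect_equal(bh_adjust(c(0.01, 0.05), m = 10), c(0.1, 0.25))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the HDI is the shortest window and matches exhaustive search", {
  h <- hdi_interval(1:1000, 0.95)
  expect_equal(unname(h[2] - h[1]), 949)
  keep <- hdi_filter(as.numeric(1:1000), 0.95)
  expect_equal(sum(!keep$keep), 50)

  x <- rep(3.7, 25)
  expect_true(all(hdi_filter(x, 0.95)$keep))

  set.seed(29)
  x <- rlnorm(400, 0, 0.6)
  h2 <- hdi_interval(x, 0.95)
  expect_equal(unname(h2), hdi_bruteforce(x, 0.95))
  removed <- x < h2[1] | x > h2[2]
  # right-skewed sample: exclusions concentrate in the right tail
  expect_gt(sum(x[removed] > median(x)), sum(x[removed] < median(x)))

  for (i in 1:8) {
    x <- rnorm(sample(30:200, 1), 1, 0.4)
    expect_equal(unname(hdi_interval(x, 0.9)), hdi_bruteforce(x, 0.9))
  }
  expect_error(hdi_interval(rnorm(10)), "at least 20")
})

test_that("interaction classification covers all six shapes and the rest", {
  expect_equal(classify_interaction(-0.02, TRUE, 0.02, TRUE),
               "opposing_enlarged_up")
  expect_equal(classify_interaction(0.02, TRUE, -0.02, TRUE),
               "opposing_enlarged_down")
  expect_equal(classify_interaction(0.001, FALSE, -0.02, TRUE),
               "enlarged_only_down")
  expect_equal(classify_interaction(0.001, FALSE, 0.02, TRUE),
               "enlarged_only_up")
  expect_equal(classify_interaction(0.02, TRUE, 0.001, FALSE),
               "reduced_only_up")
  expect_equal(classify_interaction(-0.02, TRUE, 0.001, FALSE),
               "reduced_only_down")
  expect_equal(classify_interaction(0.02, TRUE, 0.03, TRUE), "unclassified")
  expect_equal(classify_interaction(0.02, FALSE, 0.03, FALSE), "unclassified")
  expect_equal(classify_interaction(c(-1, 1), c(TRUE, TRUE), c(1, 1),
                                    c(TRUE, FALSE)),
               c("opposing_enlarged_up", "reduced_only_up"))
})

test_that("post-hoc slope tests pool BH across sites and feed categories", {
  fits <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    slope_reduced = c(-0.02, 0.001, 0.03),
    se_reduced = c(0.004, 0.01, 0.005),
    slope_enlarged = c(0.025, -0.03, 0.0005),
    se_enlarged = c(0.004, 0.005, 0.01)
  )
  ph <- posthoc_slopes(fits, rep(TRUE, 3))
  expect_equal(nrow(ph), 6)
  expect_equal(ph$p_adjusted, bh_bruteforce(ph$p_raw), tolerance = 1e-12)
  red <- ph[ph$group == "reduced", ]
  enl <- ph[ph$group == "enlarged", ]
  cats <- classify_interaction(red$slope, red$significant,
                               enl$slope, enl$significant)
  expect_equal(cats, c("opposing_enlarged_up", "enlarged_only_down",
                       "reduced_only_up"))
  empty <- posthoc_slopes(fits, rep(FALSE, 3))
  expect_equal(nrow(empty), 0)
})

test_that("planted interactions are detected and nulls stay quiet per site", {
  plan <- data.frame(category = "opposing_enlarged_up", n = 10,
                     slope_enlarged = 0.03, slope_reduced = -0.03)
  cfg <- sim_config(n_sites = 10, category_plan = plan, seed = 33,
                    baseline_logit_mix = list(weights = 1, means = 0,
                                              sds = 0.3))
  des <- simulate_design(cfg)
  sim <- simulate_methylation(des, cfg)
  tab <- run_per_site_models(sim$matrix, des)
  ok <- tab$fit_status %in% c("ok", "singular_ok")
  expect_true(all(tab$lrt_p[ok] < 1e-4))
  expect_true(all(tab$slope_enlarged[ok] > 0))
  expect_true(all(tab$slope_reduced[ok] < 0))
})

test_that("a constant site is never falsely significant", {
  cfg <- sim_config(n_sites = 1, category_plan = NULL, seed = 35)
  des <- simulate_design(cfg)
  d <- des[des$recaptured, ]
  n <- nrow(d)
  x <- meth_matrix(data.frame(chrom = "chr1", pos = 100L), d$bird_id,
                   matrix(15L, 1, n), matrix(30L, 1, n))
  tab <- run_per_site_models(x, des)
  expect_true(tab$fit_status[1] %in% c("omitted_error", "ok", "singular_ok"))
  if (tab$fit_status[1] != "omitted_error") expect_gt(tab$lrt_p[1], 0.5)
})

test_that("the pipeline telescopes, partitions categories and is deterministic", {
  plan <- default_category_plan(n_per = 10, slope = 0.03)
  cfg <- sim_config(n_sites = 150, category_plan = plan, seed = 37)
  des <- simulate_design(cfg)
  sim <- simulate_methylation(des, cfg)
  r1 <- run_dms_pipeline(sim$matrix, des)
  r2 <- run_dms_pipeline(sim$matrix, des)
  expect_identical(r1$table, r2$table)

  s <- r1$summary
  expect_equal(s$n_sites_input,
               s$n_tested + s$n_omitted_error + s$n_omitted_insufficient)
  expect_equal(s$n_in_fdr_universe, s$n_tested - s$n_removed_by_hdi)
  expect_equal(sum(unlist(s$category_counts)), s$n_significant)
  # categories of non-significant sites stay unclassified
  expect_true(all(r1$table$category[!r1$table$significant] == "unclassified"))

  # raising the q threshold never removes a significant site
  sig05 <- r1$table$q_value <= 0.05 & !is.na(r1$table$q_value)
  sig10 <- r1$table$q_value <= 0.10 & !is.na(r1$table$q_value)
  expect_true(all(sig10[sig05]))

  # widened FDR universe can only lose significance
  r3 <- run_dms_pipeline(sim$matrix, des, fdr_universe = "all_filtered")
  expect_true(all(r3$table$q_value >= r1$table$q_value, na.rm = TRUE))
})

test_that("the Manhattan diagnostic draws without error", {
  tab <- data.frame(chrom = rep(c("chr1", "chr2"), each = 20),
                    pos = rep(seq(100, 2000, by = 100), 2),
                    lrt_p = runif(40),
                    significant = rep(c(TRUE, FALSE), c(3, 37)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot_manhattan(tab))
})
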