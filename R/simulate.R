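#' Default planted-interaction plan
#'
#' One row per interaction category, giving the number of CpG sites to plant
#' and the true methylation slope (logit units per day since fledging) in
#' each treatment. The six categories are the six qualitative interaction
#' shapes used downstream: opposing slopes in the two treatments, or a slope
#' in one treatment while methylation is stable in the other.
#'
#' @param n_per sites per category.
#' @param slope absolute true slope, logit/day.
#' @return data.frame with columns `category`, `n`, `slope_enlarged`,
#'   `slope_reduced`.
#' @export
default_category_plan <- function(n_per = 100, slope = 0.025) {
  data.frame(
    category = c("opposing_enlarged_up", "opposing_enlarged_down",
                 "enlarged_only_up", "enlarged_only_down",
                 "reduced_only_up", "reduced_only_down"),
    n = n_per,
    slope_enlarged = c(slope, -slope, slope, -slope, 0, 0),
    slope_reduced  = c(-slope, slope, 0, 0, slope, -slope),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Free parameters of the synthetic-data generator. Defaults reproduce the
#' study conditions: 16 cross-foster (CF) pairs of broods manipulated by
#' +/- 3 nestlings around a base size of 9, recapture probabilities of
#' 30.51% (reduced) and 16.43% (enlarged), recapture spread uniformly over
#' 28-110 days since fledging, negative-binomial sequencing coverage around
#' 30x, and a bimodal (hypo/hyper-methylated) baseline distribution on the
#' logit scale.
#'
#' @param n_cf_pairs number of CF pairs.
#' @param base_brood_size nestlings per brood before manipulation.
#' @param manipulation nestlings moved; enlarged broods get
#'   `base_brood_size + manipulation`, reduced broods the complement.
#' @param recapture_prob_reduced,recapture_prob_enlarged per-treatment
#'   Bernoulli recapture probabilities.
#' @param days_range min/max days since fledging at recapture.
#' @param n_sites number of CpG sites to simulate.
#' @param coverage_mean,coverage_dispersion negative-binomial mean and size
#'   for per-cell read coverage.
#' @param re_sd_origin,re_sd_rearing standard deviations (logit units) of
#'   the per-site brood-of-origin and brood-of-rearing random intercepts.
#' @param baseline_logit_mix two-component normal mixture for the per-site
#'   baseline methylation on the logit scale: list with `weights`, `means`,
#'   `sds`.
#' @param category_plan data.frame as from [default_category_plan()], or
#'   `NULL` for all-null sites.
#' @param obs_overdispersion_sd per-observation Gaussian logit noise
#'   (0 = exactly binomial given the random intercepts).
#' @param seed integer seed driving all three generator streams (design,
#'   phenotypes, methylation) via fixed offsets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cf_pairs = 16,
                       base_brood_size = 9,
                       manipulation = 3,
                       recapture_prob_reduced = 0.3051,
                       recapture_prob_enlarged = 0.1643,
                       days_range = c(28, 110),
                       n_sites = 2000,
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       re_sd_origin = 0.3,
                       re_sd_rearing = 0.3,
                       baseline_logit_mix = list(weights = c(0.5, 0.5),
                                                 means = c(-1.5, 1.5),
                                                 sds = c(1, 1)),
                       category_plan = default_category_plan(),
                       obs_overdispersion_sd = 0,
                       seed = 1) {
  cfg <- list(n_cf_pairs = n_cf_pairs, base_brood_size = base_brood_size,
              manipulation = manipulation,
              recapture_prob_reduced = recapture_prob_reduced,
              recapture_prob_enlarged = recapture_prob_enlarged,
              days_range = days_range, n_sites = n_sites,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              re_sd_origin = re_sd_origin, re_sd_rearing = re_sd_rearing,
              baseline_logit_mix = baseline_logit_mix,
              category_plan = category_plan,
              obs_overdispersion_sd = obs_overdispersion_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cf_pairs >= 1, cfg$base_brood_size >= 1)
  if (cfg$manipulation < 0) stop("manipulation must be >= 0")
  if (cfg$manipulation >= cfg$base_brood_size)
    stop("manipulation must be smaller than base_brood_size")
  for (p in c(cfg$recapture_prob_reduced, cfg$recapture_prob_enlarged))
    if (!is.finite(p) || p < 0 || p > 1) stop("recapture probabilities must lie in [0, 1]")
  if (length(cfg$days_range) != 2 || cfg$days_range[1] >= cfg$days_range[2])
    stop("days_range must be (min, max) with min < max")
  if (cfg$n_sites < 0) stop("n_sites must be >= 0")
  plan <- cfg$category_plan
  if (!is.null(plan)) {
    stopifnot(all(c("category", "n", "slope_enlarged", "slope_reduced") %in% names(plan)))
    if (sum(plan$n) > cfg$n_sites)
      stop("category_plan site counts exceed n_sites")
  }
  if (cfg$n_sites == 0 && (is.null(plan) || nrow(plan) == 0))
    stop("nothing to simulate: n_sites is 0 and the category plan is empty")
  invisible(cfg)
}

# Fixed offsets make the three generator streams independently reproducible
# from one global seed.
stream_seed <- function(seed, stream = c("design", "phenotypes", "methylation")) {
  off <- c(design = 0L, phenotypes = 10007L, methylation = 20011L)
  as.integer(seed) + off[[match.arg(stream)]]
}

#' Simulate the cross-foster design
#'
#' Each CF pair contributes one enlarged and one reduced brood sharing a
#' hatch date. Nestlings are partially cross-fostered (rearing brood drawn
#' at random within the pair, so about half are moved), and recapture after
#' fledging is Bernoulli with a treatment-specific probability. Recaptured
#' birds get a days-since-fledging value drawn uniformly from
#' `days_range` and a test date equal to fledge date + days since fledging.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per nestling alive at fledging; columns
#'   `bird_id`, `cf_pair`, `treatment` (factor, reduced = reference),
#'   `brood_origin`, `brood_rearing`, `origin_in_pair`, `rearing_in_pair`,
#'   `cross_fostered`, `hatch_date` (April day), `fledge_date`,
#'   `recaptured`, `days_since_fledging`, `test_date` (NA if not
#'   recaptured).
#' @export
simulate_design <- function(config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, "design"))
  n_enl <- config$base_brood_size + config$manipulation
  n_red <- config$base_brood_size - config$manipulation

  rows <- vector("list", config$n_cf_pairs)
  for (k in seq_len(config$n_cf_pairs)) {
    pair <- sprintf("P%02d", k)
    hatch <- round(runif(1, 20, 40))      # April day
    fledge <- hatch + 20
    broods <- paste0(pair, c("a", "b"))
    # which physical brood is enlarged is random within the pair
    enlarged_brood <- sample(broods, 1)
    n_tot <- 2 * config$base_brood_size
    origin <- rep(broods, each = config$base_brood_size)
    to_enlarged <- seq_len(n_tot) %in% sample.int(n_tot, n_enl)
    rearing <- ifelse(to_enlarged, enlarged_brood, setdiff(broods, enlarged_brood))
    treatment <- ifelse(rearing == enlarged_brood, "enlarged", "reduced")
    rows[[k]] <- data.frame(
      bird_id = sprintf("%s_%02d", pair, seq_len(n_tot)),
      cf_pair = pair,
      treatment = treatment,
      brood_origin = origin,
      brood_rearing = rearing,
      cross_fostered = origin != rearing,
      hatch_date = hatch,
      fledge_date = fledge,
      stringsAsFactors = FALSE
    )
  }
  design <- do.call(rbind, rows)
  design$treatment <- factor(design$treatment, levels = c("reduced", "enlarged"))
  # nesting labels are pair-qualified, one variance per factor downstream
  design$origin_in_pair <- paste(design$cf_pair, design$brood_origin, sep = ":")
  design$rearing_in_pair <- paste(design$cf_pair, design$brood_rearing, sep = ":")

  prob <- ifelse(design$treatment == "reduced",
                 config$recapture_prob_reduced, config$recapture_prob_enlarged)
  design$recaptured <- runif(nrow(design)) < prob
  design$days_since_fledging <- NA_real_
  nr <- sum(design$recaptured)
  design$days_since_fledging[design$recaptured] <-
    runif(nr, config$days_range[1], config$days_range[2])
  design$test_date <- design$fledge_date + design$days_since_fledging

  for (tr in levels(design$treatment)) {
    if (!any(design$recaptured[design$treatment == tr]))
      stop("no recaptured individuals in the ", tr,
           " treatment; increase recapture probability or the number of CF pairs")
  }
  rownames(design) <- NULL
  design
}

#' Phenotype-generator parameters
#'
#' Linear-model effect sizes used by [simulate_phenotypes()]. Defaults mimic
#' the field study: post-fledging exploration increases by 0.21 score units
#' per day since fledging in birds from enlarged broods and is stable in
#' birds from reduced broods; third-primary (P3) growth shows the same
#' asymmetry; weight catch-up enters through a treatment-specific quadratic
#' hatch-date term in the post-fledging weight.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
phenotype_params <- function(...) {
  p <- list(
    # day-14 nestling weight (g): enlarged broods fledge lighter
    w14_intercept = 16.8, w14_treatment = -1.2, w14_sigma = 0.9,
    # post-fledging weight (g)
    wpost_intercept = 16.4,
    wpost_days_reduced = 0.03, wpost_days_enlarged = 0.03,
    wpost_hatch2_enlarged = 0.005,   # g per squared April day, enlarged only
    wpost_sigma = 0.8,
    # third primary length (mm)
    p3_intercept = 62,
    p3_days_reduced = -0.01, p3_days_enlarged = 0.04, p3_sigma = 1.2,
    # exploration score (movement units, date-corrected scale)
    expl_intercept = 10,
    expl_days_reduced = 0.002, expl_days_enlarged = 0.21, expl_sigma = 2,
    # brood-level random intercepts, shared scale across traits
    re_sd_origin = 0.4, re_sd_rearing = 0.4
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown phenotype parameters: ",
                            paste(unknown, collapse = ", "))
  p <- modifyList(p, dots)
  if (!all(vapply(p, function(x) is.numeric(x) && all(is.finite(x)), TRUE)))
    stop("phenotype parameters must be finite numbers")
  p
}

#' Simulate post-fledging phenotypes
#'
#' Generates day-14 weight, post-fledging weight, P3 length and exploration
#' score for the recaptured individuals of a simulated design, as linear
#' functions of treatment, days since fledging and hatch date (squared, for
#' the weight catch-up term), plus brood-of-origin and brood-of-rearing
#' random intercepts and Gaussian noise.
#'
#' @param design from [simulate_design()].
#' @param params from [phenotype_params()].
#' @param seed integer seed for this stream.
#' @return data.frame of phenotype records (recaptured individuals only)
#'   with `delta_weight = weight_post - weight_day14`.
#' @export
simulate_phenotypes <- function(design, params = phenotype_params(), seed = 1) {
  params <- do.call(phenotype_params, params)   # validates and fills defaults
  set.seed(stream_seed(seed, "phenotypes"))

  d <- design[design$recaptured, , drop = FALSE]
  if (nrow(d) == 0) stop("design has no recaptured individuals")
  enl <- as.numeric(d$treatment == "enlarged")
  days <- d$days_since_fledging
  hatch2 <- d$hatch_date^2

  ran <- function(ids, sd) {
    u <- rnorm(length(unique(ids)), 0, sd)
    names(u) <- unique(ids)
    u[ids]
  }
  re <- function() ran(d$origin_in_pair, params$re_sd_origin) +
    ran(d$rearing_in_pair, params$re_sd_rearing)

  w14 <- params$w14_intercept + params$w14_treatment * enl + re() +
    rnorm(nrow(d), 0, params$w14_sigma)
  wpost <- params$wpost_intercept +
    (params$wpost_days_reduced * (1 - enl) + params$wpost_days_enlarged * enl) * days +
    params$wpost_hatch2_enlarged * enl * (hatch2 - mean(hatch2)) + re() +
    rnorm(nrow(d), 0, params$wpost_sigma)
  p3 <- params$p3_intercept +
    (params$p3_days_reduced * (1 - enl) + params$p3_days_enlarged * enl) * days +
    re() + rnorm(nrow(d), 0, params$p3_sigma)
  expl <- params$expl_intercept +
    (params$expl_days_reduced * (1 - enl) + params$expl_days_enlarged * enl) * days +
    re() + rnorm(nrow(d), 0, params$expl_sigma)

  out <- d[, c("bird_id", "treatment", "cf_pair", "brood_origin",
               "brood_rearing", "origin_in_pair", "rearing_in_pair",
               "hatch_date", "days_since_fledging", "test_date")]
  out$weight_day14 <- w14
  out$weight_post <- wpost
  out$delta_weight <- wpost - w14
  out$p3_length <- p3
  out$movement_count <- pmax(0, round(expl))
  out$exploration_score <- expl
  rownames(out) <- NULL
  out
}

#' Simulate per-CpG methylation counts
#'
#' For every site and recaptured individual, coverage is drawn from a
#' negative binomial and the methylated count from a binomial whose success
#' probability follows
#' `logit(p) = baseline + slope[treatment] * days + u_origin + u_rearing`,
#' with optional per-observation Gaussian overdispersion on the logit scale.
#' Sites in the category plan carry the planted treatment-specific slopes;
#' the remaining sites are null (both slopes zero).
#'
#' @param design from [simulate_design()].
#' @param config a [sim_config()].
#' @return list with `matrix` (a [meth_matrix]) and `truth` (one row per
#'   site: category, true slopes, baseline logit).
#' @export
simulate_methylation <- function(design, config) {
  validate_sim_config(config)
  d <- design[design$recaptured, , drop = FALSE]
  for (tr in levels(design$treatment))
    if (!any(d$treatment == tr))
      stop("need at least one recaptured individual per treatment")
  set.seed(stream_seed(config$seed, "methylation"))

  n_ind <- nrow(d)
  n_sites <- config$n_sites
  plan <- config$category_plan
  cat_lab <- rep("null", n_sites)
  sl_e <- sl_r <- rep(0, n_sites)
  if (!is.null(plan) && nrow(plan) > 0) {
    idx <- 1L
    for (i in seq_len(nrow(plan))) {
      if (plan$n[i] == 0) next
      take <- idx:(idx + plan$n[i] - 1L)
      cat_lab[take] <- plan$category[i]
      sl_e[take] <- plan$slope_enlarged[i]
      sl_r[take] <- plan$slope_reduced[i]
      idx <- idx + plan$n[i]
    }
  }

  mix <- config$baseline_logit_mix
  comp <- sample.int(length(mix$weights), n_sites, replace = TRUE, prob = mix$weights)
  baseline <- rnorm(n_sites, mix$means[comp], mix$sds[comp])

  enl <- as.numeric(d$treatment == "enlarged")
  days <- d$days_since_fledging
  days_c <- days - mean(days)   # centering keeps baseline the mid-study level

  o_ids <- factor(d$origin_in_pair)
  r_ids <- factor(d$rearing_in_pair)
  meth <- tot <- matrix(NA_integer_, n_sites, n_ind)
  for (s in seq_len(n_sites)) {
    u_o <- rnorm(nlevels(o_ids), 0, config$re_sd_origin)[as.integer(o_ids)]
    u_r <- rnorm(nlevels(r_ids), 0, config$re_sd_rearing)[as.integer(r_ids)]
    eta <- baseline[s] + (sl_e[s] * enl + sl_r[s] * (1 - enl)) * days_c + u_o + u_r
    if (config$obs_overdispersion_sd > 0)
      eta <- eta + rnorm(n_ind, 0, config$obs_overdispersion_sd)
    nn <- rnbinom(n_ind, mu = config$coverage_mean, size = config$coverage_dispersion)
    meth[s, ] <- rbinom(n_ind, nn, plogis(eta))
    tot[s, ] <- nn
  }

  sites <- data.frame(chrom = "chr1", pos = 100L + 50L * (seq_len(n_sites) - 1L),
                      stringsAsFactors = FALSE)
  mat <- meth_matrix(sites, d$bird_id, meth, tot)
  truth <- data.frame(chrom = sites$chrom, pos = sites$pos,
                      category = cat_lab, slope_enlarged = sl_e,
                      slope_reduced = sl_r, baseline_logit = baseline,
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}
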