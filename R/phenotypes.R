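#' Date-corrected exploration score
#'
#' The raw movement count of the 2-minute novel-environment test is
#' corrected for test date by linear residualisation across the cohort;
#' the cohort grand mean is added back so the score keeps the original
#' scale. With a single distinct test date the correction is skipped with
#' a warning and raw counts are returned.
#'
#' @param movement_count non-negative movement counts.
#' @param test_date numeric test date (e.g. day of year).
#' @return numeric exploration scores.
#' @export
compute_exploration_score <- function(movement_count, test_date) {
  if (any(movement_count < 0)) stop("movement counts must be >= 0")
  if (length(movement_count) != length(test_date))
    stop("movement_count and test_date lengths differ")
  if (length(unique(test_date)) < 2) {
    warning("only one distinct test date: date correction skipped")
    return(as.numeric(movement_count))
  }
  fit <- lm(movement_count ~ test_date)
  as.numeric(residuals(fit)) + mean(movement_count)
}

#' Spearman rank-order correlation with t-approximation
#'
#' Rank correlation using average ranks for ties; the p-value uses the
#' t-distribution approximation on n - 2 degrees of freedom.
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_check <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant vector: rank correlation undefined")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Analyse the post-fledging phenotypes
#'
#' Runs the biometric/behavioural stage on a phenotype table: for
#' post-fledging weight, delta weight (post-fledging minus day-14 weight),
#' P3 length and exploration score, fits a Gaussian mixed model with
#' brood-of-origin and brood-of-rearing (pair-qualified) random
#' intercepts, applies backward elimination of fixed effects (treatment
#' always kept; interactions and the squared hatch-date term go first),
#' reports the type III Satterthwaite F table of the final model and, when
#' the days-since-fledging term survives, per-treatment slopes of days
#' with Bonferroni correction. For delta weight the initial model
#' additionally carries hatch date, its square, and their interactions
#' with treatment.
#'
#' @param table phenotype records as from [simulate_phenotypes()]; required
#'   columns: `treatment`, `days_since_fledging`, `hatch_date`,
#'   `origin_in_pair`, `rearing_in_pair`, and the four responses
#'   (`weight_post`, `delta_weight`, `p3_length`, `exploration_score`).
#' @param alpha elimination threshold.
#' @return named list (one element per response) with `fit`, `anova`,
#'   `trace`, `final_terms` and `slopes` (NULL when days was eliminated).
#' @export
analyze_phenotypes <- function(table, alpha = 0.05) {
  need <- c("treatment", "days_since_fledging", "hatch_date",
            "origin_in_pair", "rearing_in_pair", "weight_post",
            "delta_weight", "p3_length", "exploration_score")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  table$treatment <- factor(table$treatment, levels = c("reduced", "enlarged"))
  table$hatch_sq <- table$hatch_date^2
  re <- "(1 | origin_in_pair) + (1 | rearing_in_pair)"
  squares <- c(hatch_sq = "hatch_date")

  specs <- list(
    weight_post = paste("weight_post ~ treatment * days_since_fledging +", re),
    delta_weight = paste(
      "delta_weight ~ treatment + hatch_date + hatch_sq +",
      "treatment:hatch_date + treatment:hatch_sq +",
      "days_since_fledging + treatment:days_since_fledging +", re),
    p3_length = paste("p3_length ~ treatment * days_since_fledging +", re),
    exploration_score =
      paste("exploration_score ~ treatment * days_since_fledging +", re)
  )

  out <- lapply(names(specs), function(resp) {
    el <- backward_eliminate(as.formula(specs[[resp]]), table, alpha = alpha,
                             always_keep = "treatment", squares = squares)
    slopes <- NULL
    if ("days_since_fledging" %in% el$final_terms ||
        any(grepl("days_since_fledging", el$final_terms)))
      slopes <- lmm_slope_trends(el$fit, "days_since_fledging")
    hatch_slopes <- NULL
    if (any(grepl("hatch_sq", el$final_terms)))
      hatch_slopes <- lmm_slope_trends(el$fit, "hatch_sq")
    list(fit = el$fit, anova = type3_anova_satterthwaite(el$fit),
         trace = el$trace, final_terms = el$final_terms,
         slopes = slopes, hatch_slopes = hatch_slopes)
  })
  names(out) <- names(specs)
  out
}
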