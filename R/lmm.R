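#' Fit a Gaussian linear mixed model by maximum likelihood
#'
#' Thin wrapper around `lmerTest::lmer(..., REML = FALSE)` so downstream
#' code (type III tests with Satterthwaite degrees of freedom, slope
#' trends, backward elimination) has a single entry point. ML, not REML,
#' so that fixed-effect terms can be compared across nested models during
#' elimination.
#'
#' @param formula full lmer formula including random-intercept terms,
#'   e.g. `y ~ treatment * days_since_fledging + (1 | origin_in_pair) +
#'   (1 | rearing_in_pair)`.
#' @param data model data.
#' @param reml set `TRUE` for a REML fit (e.g. when exact balanced-design
#'   degrees of freedom are wanted); the analysis stage always uses ML.
#' @return an `lmerModLmerTest` fit.
#' @export
fit_lmm_ml <- function(formula, data, reml = FALSE) {
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, REML = reml))
  msgs <- fit@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  if (length(msgs))
    warning("lmm convergence messages: ", paste(msgs, collapse = "; "))
  fit
}

#' Type III ANOVA with Satterthwaite degrees of freedom
#'
#' @param fit an `lmerModLmerTest` fit from [fit_lmm_ml()].
#' @return the per-term F table (data.frame with `F value`, `NumDF`,
#'   `DenDF`, `Pr(>F)`).
#' @export
type3_anova_satterthwaite <- function(fit) {
  stopifnot(inherits(fit, "lmerModLmerTest"))
  as.data.frame(anova(fit, type = "III", ddf = "Satterthwaite"))
}

# ---- term bookkeeping for backward elimination -------------------------

# Map a fixed term label to named powers per variable, treating I(x^2)
# (or a plain squared column such as hatch_sq declared via `squares`)
# as x to the power 2, so that quadratic terms are removed before their
# linear parent.
term_powers <- function(label, squares = character()) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  pow <- list()
  for (p in parts) {
    mm <- regmatches(p, regexec("^I\\((\\w+)\\^([0-9]+)\\)$", p))[[1]]
    if (length(mm) == 3) {
      v <- mm[2]; k <- as.numeric(mm[3])
    } else if (p %in% names(squares)) {
      v <- squares[[p]]; k <- 2
    } else {
      v <- p; k <- 1
    }
    pow[[v]] <- max(pow[[v]] %||% 0, k)
  }
  pow
}

term_contains <- function(big, small, squares = character()) {
  pb <- term_powers(big, squares); ps <- term_powers(small, squares)
  if (identical(pb, ps)) return(FALSE)
  all(vapply(names(ps), function(v)
    !is.null(pb[[v]]) && pb[[v]] >= ps[[v]], TRUE))
}

#' Backward elimination of fixed effects
#'
#' Refits by ML, repeatedly removing the least-significant removable term
#' with p >= `alpha` from the type III Satterthwaite table. A term is
#' removable only when it is not contained in any retained higher-order
#' term (interactions go before their main effects; a squared term counts
#' as containing its linear parent, so e.g. hatch-date-squared is removed
#' before hatch date). Terms in `always_keep` are never removed. Ties in p
#' are broken in favour of the term appearing later in the model.
#'
#' @param formula initial model formula (fixed + random parts).
#' @param data model data.
#' @param alpha retention threshold on the type III p-value.
#' @param always_keep fixed terms never eliminated (the treatment term, by
#'   default).
#' @param squares named character vector declaring plain columns that are
#'   squares of other columns, e.g. `c(hatch_sq = "hatch_date")`.
#' @return list with `fit` (final model), `trace` (data.frame of removed
#'   terms and their p at removal) and `final_terms`.
#' @export
backward_eliminate <- function(formula, data, alpha = 0.05,
                               always_keep = "treatment",
                               squares = character()) {
  rhs_random <- attr(terms(formula), "term.labels")
  rand_part <- grep("\\|", rhs_random, value = TRUE)
  fixed_terms <- setdiff(rhs_random, rand_part)
  response <- deparse(formula[[2]])
  trace <- data.frame(term = character(), p = numeric(),
                      stringsAsFactors = FALSE)

  build <- function(fx) {
    as.formula(paste(response, "~",
                     paste(c(fx %||% "1",
                             paste0("(", rand_part, ")")), collapse = " + ")))
  }

  repeat {
    fit <- fit_lmm_ml(build(fixed_terms), data)
    tab <- type3_anova_satterthwaite(fit)
    pvals <- setNames(tab[["Pr(>F)"]], rownames(tab))
    removable <- fixed_terms[!fixed_terms %in% always_keep]
    removable <- removable[vapply(removable, function(tm)
      !any(vapply(setdiff(fixed_terms, tm), term_contains, TRUE,
                  small = tm, squares = squares)), TRUE)]
    cand <- removable[removable %in% names(pvals) &
                        pvals[removable] >= alpha]
    if (length(cand) == 0) {
      return(list(fit = fit, trace = trace, final_terms = fixed_terms))
    }
    # highest p first; ties broken by reverse model order
    ord <- order(-pvals[cand], -match(cand, fixed_terms))
    drop_term <- cand[ord][1]
    trace <- rbind(trace, data.frame(term = drop_term,
                                     p = unname(pvals[drop_term])))
    fixed_terms <- setdiff(fixed_terms, drop_term)
  }
}

#' Per-treatment slope trends for a Gaussian fit
#'
#' Estimated marginal trends of `var` by treatment with Bonferroni-adjusted
#' significance tests (`emmeans::emtrends`).
#'
#' @param fit an `lmerModLmerTest` fit containing `var`.
#' @param var continuous variable whose per-treatment slope is wanted.
#' @param by_factor grouping factor (default treatment).
#' @param adjust adjustment passed to the test (default bonferroni).
#' @return data.frame with one row per level: trend, SE, df, t, p.
#' @export
lmm_slope_trends <- function(fit, var, by_factor = "treatment",
                             adjust = "bonferroni") {
  tr <- emmeans::emtrends(fit, stats::reformulate(by_factor), var = var,
                          lmer.df = "satterthwaite")
  as.data.frame(emmeans::test(tr, adjust = adjust))
}
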