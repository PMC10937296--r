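#' Fit a binomial logit mixed model by Laplace approximation
#'
#' The estimation engine behind the per-CpG screening models: a binomial
#' GLMM with logit link and independent random intercepts (one variance
#' component per grouping factor, each expressed as a factor nested within
#' CF pair by using pair-qualified labels). Random-effect standard
#' deviations are optimised on the log scale over the Laplace-approximated
#' marginal likelihood; fixed effects are profiled out by a penalised
#' iteratively reweighted least-squares step to the joint mode.
#'
#' @param meth,total integer vectors of methylated and total counts
#'   (`meth <= total`, `total >= 1`).
#' @param data data.frame holding the fixed-effect covariates and grouping
#'   factors.
#' @param fixed one-sided formula of fixed-effect terms,
#'   e.g. `~ treatment * days_since_fledging`.
#' @param random character vector of grouping-factor column names
#'   (`NULL` or empty for an ordinary logistic regression).
#' @return object of class `bin_glmm`: fixed-effect estimates and their
#'   covariance, random-effect standard deviations, Laplace log-likelihood,
#'   fitted probabilities (including predicted random effects),
#'   convergence/singularity/separation flags, and the Pearson dispersion.
#' @export
fit_binomial_glmm <- function(meth, total, data,
                              fixed = ~ treatment * days_since_fledging,
                              random = c("origin_in_pair", "rearing_in_pair")) {
  if (length(meth) != nrow(data) || length(total) != nrow(data))
    stop("meth/total length must match data rows")
  if (any(total < 1)) stop("all totals must be >= 1")
  if (any(meth < 0) || any(meth > total)) stop("need 0 <= meth <= total")
  keep01 <- vapply(all.vars(fixed), function(v) is.numeric(data[[v]]) ||
                     is.factor(data[[v]]) || is.character(data[[v]]), TRUE)
  if (!all(keep01)) stop("unsupported covariate type in fixed formula")

  X <- model.matrix(fixed, data)
  if (qr(X)$rank < ncol(X)) {
    ok <- qr(X)$pivot[seq_len(qr(X)$rank)]
    stop("rank-deficient fixed-effect design; aliased terms: ",
         paste(colnames(X)[-ok], collapse = ", "))
  }
  random <- random[nzchar(random %||% character())]
  facs <- lapply(random, function(v) factor(data[[v]]))
  Z <- if (length(facs))
    do.call(cbind, lapply(facs, function(f)
      model.matrix(~ 0 + f)[, , drop = FALSE]))
  else matrix(0, nrow(X), 0)
  facsize <- vapply(facs, nlevels, 1L)

  separation <- all(meth == 0) || all(meth == total)
  if (separation)
    warning("all responses at 0 or at the maximum: complete separation, ",
            "fit flagged")

  m <- as.numeric(meth); tt <- as.numeric(total)
  nfac <- length(facsize)
  if (nfac > 0) {
    obj <- function(th) {
      r <- glmm_laplace_eval(m, tt, X, Z, facsize, th, FALSE)
      if (!is.finite(r$loglik)) return(1e10)
      -r$loglik
    }
    opt <- nlminb(rep(log(0.3), nfac), obj,
                  lower = rep(-8, nfac), upper = rep(3, nfac),
                  control = list(rel.tol = 1e-10, iter.max = 500))
    theta <- opt$par
    converged <- opt$convergence == 0
  } else {
    theta <- numeric(0)
    converged <- TRUE
  }
  fit <- glmm_laplace_eval(m, tt, X, Z, facsize, theta, TRUE)
  converged <- converged && isTRUE(fit$ok)
  if (!converged) warning("binomial GLMM did not converge")

  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  vcov_beta <- fit$vcov_beta
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  sds <- exp(theta)
  names(sds) <- random
  singular <- nfac > 0 && any(sds < 1e-4)

  p_hat <- pmin(1 - 1e-10, pmax(1e-10, drop(fit$fitted)))
  pearson <- sum((m - tt * p_hat)^2 / (tt * p_hat * (1 - p_hat)))
  res_df <- length(m) - ncol(X)   # fixed-effect parameters only

  structure(list(beta = beta, vcov_beta = vcov_beta,
                 sd_components = sds,
                 var_components = setNames(sds^2, random),
                 loglik = fit$loglik, converged = converged,
                 singular = singular, separation = separation,
                 n_obs = length(m), n_par = ncol(X),
                 fitted = p_hat,
                 pearson_dispersion = if (res_df > 0) pearson / res_df else NA_real_,
                 fixed = fixed, random = random,
                 xlevels = lapply(Filter(is.factor,
                                         data[all.vars(fixed)]), levels),
                 data = data),
            class = "bin_glmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print bin_glmm
#' @export
print.bin_glmm <- function(x, ...) {
  cat("Binomial logit mixed model (Laplace)\n")
  cat("  log-likelihood:", format(x$loglik), " n =", x$n_obs, "\n")
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  if (length(x$sd_components)) {
    cat("  random-intercept sd:\n")
    print(round(x$sd_components, 4))
  }
  if (x$singular) cat("  (singular fit: a variance component is at zero)\n")
  if (!x$converged) cat("  (NOT converged)\n")
  invisible(x)
}

#' Pearson dispersion statistic
#'
#' Sum over observations of squared Pearson residuals (with fitted
#' probabilities at the joint mode, i.e. including predicted random
#' effects) divided by the residual degrees of freedom
#' `n_obs - n_fixed_parameters`. Approximately 1 under binomial variation.
#'
#' @param fit a `bin_glmm`.
#' @return unitless ratio.
#' @export
pearson_dispersion <- function(fit) {
  stopifnot(inherits(fit, "bin_glmm"))
  fit$pearson_dispersion
}

#' Likelihood-ratio test between nested fits
#'
#' `statistic = 2 * (loglik_full - loglik_null)`, degrees of freedom the
#' difference in fixed-effect parameter count, p-value from the upper tail
#' of the chi-square distribution. Small negative statistics (within
#' 1e-6) are clamped to zero.
#'
#' @param fit_null,fit_full nested `bin_glmm` fits on the same rows with
#'   the same random structure.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "bin_glmm"), inherits(fit_full, "bin_glmm"))
  if (fit_null$n_obs != fit_full$n_obs)
    stop("fits are on different numbers of observations")
  if (!identical(fit_null$random, fit_full$random))
    stop("fits have different random structures")
  if (!all(names(fit_null$beta) %in% names(fit_full$beta)))
    stop("models are not nested: null terms ",
         paste(setdiff(names(fit_null$beta), names(fit_full$beta)),
               collapse = ", "), " absent from the full model")
  df <- fit_full$n_par - fit_null$n_par
  if (df <= 0) stop("full model must add fixed-effect parameters")
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  if (stat < 0) {
    if (stat < -1e-6)
      warning("likelihood ratio statistic negative beyond tolerance (",
              format(stat), "); clamped to 0")
    stat <- 0
  }
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Per-group slope contrasts
#'
#' For each level of `by_factor`, the slope of `slope_var` is the linear
#' combination of the slope coefficient and (for non-reference levels) the
#' corresponding interaction coefficient; standard errors come from the
#' delta method on the fixed-effect covariance; p-values are two-sided
#' normal.
#'
#' @param fit a `bin_glmm`.
#' @param slope_var name of the continuous slope variable.
#' @param by_factor name of the grouping factor (omit or set `NULL` for a
#'   single shared slope).
#' @param adjust multiplicity adjustment across the returned contrasts:
#'   `"none"`, `"bonferroni"` or `"BH"`.
#' @param alpha significance level for the `significant` flag (applied to
#'   the adjusted p-value).
#' @return data.frame with one row per group: `group`, `slope`, `se`,
#'   `statistic`, `p_raw`, `p_adjusted`, `significant`.
#' @export
slope_contrasts <- function(fit, slope_var = "days_since_fledging",
                            by_factor = "treatment",
                            adjust = c("none", "bonferroni", "BH"),
                            alpha = 0.05) {
  stopifnot(inherits(fit, "bin_glmm"))
  adjust <- match.arg(adjust)
  cn <- names(fit$beta)
  if (!slope_var %in% cn)
    stop("slope variable '", slope_var, "' not in the model")
  levs <- if (!is.null(by_factor) && by_factor %in% names(fit$xlevels))
    fit$xlevels[[by_factor]] else NULL
  groups <- levs %||% "all"

  rows <- lapply(groups, function(g) {
    contrast <- setNames(numeric(length(cn)), cn)
    contrast[slope_var] <- 1
    if (!is.null(levs) && g != levs[1]) {
      inter <- c(paste0(by_factor, g, ":", slope_var),
                 paste0(slope_var, ":", by_factor, g))
      hit <- inter[inter %in% cn]
      if (length(hit)) contrast[hit[1]] <- 1
    }
    slope <- sum(contrast * fit$beta)
    se <- sqrt(drop(t(contrast) %*% fit$vcov_beta %*% contrast))
    z <- slope / se
    data.frame(group = g, slope = slope, se = se, statistic = z,
               p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(adjust,
                           none = out$p_raw,
                           bonferroni = pmin(1, out$p_raw * nrow(out)),
                           BH = p.adjust(out$p_raw, "BH"))
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
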