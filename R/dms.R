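#' Benjamini-Hochberg adjustment with missing-value bookkeeping
#'
#' Step-up BH q-values, preserving input order. `NA`/`NaN` p-values
#' propagate as `NA` and are excluded from the number of tests. The
#' effective number of tests can be widened with `m` (e.g. to use the full
#' filtered-site universe rather than the tested set).
#'
#' @param p p-values in `[0, 1]` (NA allowed).
#' @param m number of tests; default the number of non-missing p-values.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p, m = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- m %||% sum(ok)
  if (m < sum(ok)) stop("m cannot be smaller than the number of p-values")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH", n = m)
  out
}

#' Highest-density interval of an empirical distribution
#'
#' The shortest contiguous window of the sorted values containing
#' `ceiling(mass * N)` observations; ties between equally short windows are
#' broken by the lowest starting value.
#'
#' @param x finite numeric values, length >= 20 (shorter samples make the
#'   interval unstable).
#' @param mass probability mass, in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
hdi_interval <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("need at least 20 finite values for a stable HDI")
  xs <- sort(x)
  k <- ceiling(mass * n)
  widths <- xs[k:n] - xs[1:(n - k + 1)]
  i <- which.min(widths)   # which.min takes the first (lowest start) on ties
  c(lower = xs[i], upper = xs[i + k - 1])
}

#' Overdispersion filter by highest-density interval
#'
#' Keeps sites whose dispersion statistic falls inside the `mass` highest
#' density interval of the empirical dispersion distribution.
#'
#' @param dispersions per-site Pearson dispersion statistics.
#' @param mass HDI mass (default 0.95).
#' @return list with `keep` (logical, NA dispersions are dropped) and
#'   `interval`.
#' @export
hdi_filter <- function(dispersions, mass = 0.95) {
  interval <- hdi_interval(dispersions, mass)
  keep <- is.finite(dispersions) &
    dispersions >= interval[1] & dispersions <= interval[2]
  list(keep = keep, interval = interval)
}

#' Fit the null and full model for every CpG
#'
#' Per site: a null binomial GLMM with treatment only, and a full model
#' with treatment, days since fledging and their interaction, both with
#' brood-of-origin and brood-of-rearing random intercepts (pair-qualified
#' labels); the likelihood-ratio test between them (2 df) screens for
#' days-dependent treatment effects. Sites whose fits error are marked
#' `omitted_error` (singular fits are kept, flagged `singular_ok`); sites
#' with fewer than 2 covered individuals in either treatment are
#' `omitted_insufficient`.
#'
#' @param x a filtered [meth_matrix].
#' @param design design table covering all matrix samples (`bird_id`,
#'   `treatment`, `days_since_fledging`, `origin_in_pair`,
#'   `rearing_in_pair`).
#' @return data.frame, one row per site: coordinates, n_obs, log-likelihoods,
#'   LRT statistic/df/p, Pearson dispersion of the full model, per-treatment
#'   slope estimates and standard errors, `fit_status`.
#' @export
run_per_site_models <- function(x, design) {
  validate_meth_matrix(x)
  idx <- match(x$samples, design$bird_id)
  if (anyNA(idx)) stop("samples missing from design: ",
                       paste(x$samples[is.na(idx)], collapse = ", "))
  d <- design[idx, , drop = FALSE]
  d$treatment <- factor(d$treatment, levels = c("reduced", "enlarged"))

  n_sites <- nrow(x$sites)
  res <- data.frame(
    chrom = x$sites$chrom, pos = x$sites$pos,
    n_obs = NA_integer_, loglik_null = NA_real_, loglik_full = NA_real_,
    lrt_stat = NA_real_, lrt_df = NA_integer_, lrt_p = NA_real_,
    dispersion = NA_real_,
    slope_reduced = NA_real_, se_reduced = NA_real_,
    slope_enlarged = NA_real_, se_enlarged = NA_real_,
    fit_status = rep("ok", n_sites), stringsAsFactors = FALSE
  )

  for (s in seq_len(n_sites)) {
    cov <- !is.na(x$total[s, ]) & x$total[s, ] >= 1
    ds <- d[cov, , drop = FALSE]
    if (sum(ds$treatment == "reduced") < 2 ||
        sum(ds$treatment == "enlarged") < 2) {
      res$fit_status[s] <- "omitted_insufficient"
      next
    }
    m <- x$meth[s, cov]
    tt <- x$total[s, cov]
    out <- tryCatch({
      withCallingHandlers({
        f0 <- fit_binomial_glmm(m, tt, ds, fixed = ~ treatment)
        f1 <- fit_binomial_glmm(m, tt, ds,
                                fixed = ~ treatment * days_since_fledging)
        lrt <- likelihood_ratio_test(f0, f1)
        sl <- slope_contrasts(f1, "days_since_fledging", "treatment",
                              adjust = "none")
        list(f0 = f0, f1 = f1, lrt = lrt, sl = sl)
      }, warning = function(w) {
        # the study keeps fits whose only warning is a singularity;
        # singularity is detected from the fit itself, so warnings from
        # the optimiser are the "error warnings" that omit a site
        if (!grepl("singular", conditionMessage(w), ignore.case = TRUE))
          stop(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    }, error = function(e) NULL)
    if (is.null(out) || !out$f0$converged || !out$f1$converged ||
        out$f0$separation || out$f1$separation) {
      res$fit_status[s] <- "omitted_error"
      next
    }
    res$n_obs[s] <- out$f1$n_obs
    res$loglik_null[s] <- out$f0$loglik
    res$loglik_full[s] <- out$f1$loglik
    res$lrt_stat[s] <- out$lrt$statistic
    res$lrt_df[s] <- out$lrt$df
    res$lrt_p[s] <- out$lrt$p_value
    res$dispersion[s] <- pearson_dispersion(out$f1)
    res$slope_reduced[s] <- out$sl$slope[out$sl$group == "reduced"]
    res$se_reduced[s] <- out$sl$se[out$sl$group == "reduced"]
    res$slope_enlarged[s] <- out$sl$slope[out$sl$group == "enlarged"]
    res$se_enlarged[s] <- out$sl$se[out$sl$group == "enlarged"]
    if (out$f0$singular || out$f1$singular)
      res$fit_status[s] <- "singular_ok"
  }
  res
}

#' Post-hoc per-treatment slope tests for significant sites
#'
#' Normal-reference z-tests of the reduced and enlarged slopes of each
#' significant site, with BH correction applied jointly across all
#' `2 * n_significant` tests (or per site with `pool = "per_site"`).
#'
#' @param site_fits output of [run_per_site_models()].
#' @param significant logical vector marking the significant sites.
#' @param alpha significance level on the adjusted p-values.
#' @param pool `"joint"` (default) or `"per_site"` BH pool.
#' @return data.frame, two rows (reduced, enlarged) per significant site.
#' @export
posthoc_slopes <- function(site_fits, significant, alpha = 0.05,
                           pool = c("joint", "per_site")) {
  pool <- match.arg(pool)
  sig <- site_fits[which(significant), , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      group = character(), slope = numeric(), se = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  long <- rbind(
    data.frame(chrom = sig$chrom, pos = sig$pos, group = "reduced",
               slope = sig$slope_reduced, se = sig$se_reduced,
               stringsAsFactors = FALSE),
    data.frame(chrom = sig$chrom, pos = sig$pos, group = "enlarged",
               slope = sig$slope_enlarged, se = sig$se_enlarged,
               stringsAsFactors = FALSE))
  long$p_raw <- 2 * pnorm(-abs(long$slope / long$se))
  if (pool == "joint") {
    long$p_adjusted <- bh_adjust(long$p_raw)
  } else {
    key <- paste(long$chrom, long$pos)
    long$p_adjusted <- stats::ave(long$p_raw, key,
                                  FUN = function(p) bh_adjust(p))
  }
  long$significant <- !is.na(long$p_adjusted) & long$p_adjusted < alpha
  long
}

#' Classify a site's interaction shape
#'
#' Maps the two post-hoc slope verdicts onto the six interaction
#' categories: opposing slopes (enlarged up / enlarged down), a slope in
#' the enlarged treatment only (up / down), or in the reduced treatment
#' only (up / down). Combinations outside the six shapes (neither slope
#' significant, or both significant with the same sign) are
#' `unclassified`.
#'
#' @param slope_reduced,slope_enlarged slope estimates.
#' @param sig_reduced,sig_enlarged post-FDR significance flags.
#' @return character vector of category labels.
#' @export
classify_interaction <- function(slope_reduced, sig_reduced,
                                 slope_enlarged, sig_enlarged) {
  n <- length(slope_reduced)
  out <- rep("unclassified", n)
  both <- sig_reduced & sig_enlarged
  out[both & slope_enlarged > 0 & slope_reduced < 0] <- "opposing_enlarged_up"
  out[both & slope_enlarged < 0 & slope_reduced > 0] <- "opposing_enlarged_down"
  eonly <- sig_enlarged & !sig_reduced
  out[eonly & slope_enlarged > 0] <- "enlarged_only_up"
  out[eonly & slope_enlarged < 0] <- "enlarged_only_down"
  ronly <- sig_reduced & !sig_enlarged
  out[ronly & slope_reduced > 0] <- "reduced_only_up"
  out[ronly & slope_reduced < 0] <- "reduced_only_down"
  out
}

#' Run the per-CpG differential-methylation pipeline
#'
#' Order of operations: per-site null/full fits -> omit errored sites ->
#' overdispersion filter (95% HDI of the full-model Pearson dispersion) ->
#' BH-FDR on the remaining likelihood-ratio p-values -> post-hoc slope
#' tests with their own BH pool -> six-category classification.
#'
#' @param x filtered [meth_matrix].
#' @param design design table.
#' @param fdr q-value threshold for days-dependent DMS.
#' @param hdi_mass HDI mass for the dispersion filter.
#' @param fdr_universe `"tested"` (default; number of tests = sites
#'   surviving omission and the HDI filter) or `"all_filtered"` (= all
#'   sites in the input matrix).
#' @param posthoc_pool BH pool for the slope tests, `"joint"` or
#'   `"per_site"`.
#' @return list with `table` (per-site DMS records incl. q-values,
#'   `kept_by_hdi`, category), `posthoc` (slope test rows), and `summary`
#'   (telescoping counts and per-category tallies).
#' @export
run_dms_pipeline <- function(x, design, fdr = 0.05, hdi_mass = 0.95,
                             fdr_universe = c("tested", "all_filtered"),
                             posthoc_pool = "joint") {
  fdr_universe <- match.arg(fdr_universe)
  tab <- run_per_site_models(x, design)

  tab$kept_by_hdi <- FALSE
  tested <- tab$fit_status %in% c("ok", "singular_ok")
  hd <- hdi_filter(tab$dispersion[tested], hdi_mass)
  tab$kept_by_hdi[tested] <- hd$keep

  tab$q_value <- NA_real_
  universe <- if (fdr_universe == "tested") sum(tab$kept_by_hdi) else nrow(tab)
  tab$q_value[tab$kept_by_hdi] <-
    bh_adjust(tab$lrt_p[tab$kept_by_hdi], m = universe)
  tab$significant <- !is.na(tab$q_value) & tab$q_value <= fdr

  ph <- posthoc_slopes(tab, tab$significant, alpha = fdr, pool = posthoc_pool)
  tab$category <- "unclassified"
  if (nrow(ph) > 0) {
    key <- paste(tab$chrom, tab$pos)
    red <- ph[ph$group == "reduced", ]
    enl <- ph[ph$group == "enlarged", ]
    i <- match(paste(red$chrom, red$pos), key)
    tab$category[i] <- classify_interaction(
      red$slope, red$significant,
      enl$slope[match(paste(red$chrom, red$pos), paste(enl$chrom, enl$pos))],
      enl$significant[match(paste(red$chrom, red$pos),
                            paste(enl$chrom, enl$pos))])
  }
  tab$category[!tab$significant] <- "unclassified"

  cats <- c("opposing_enlarged_up", "opposing_enlarged_down",
            "enlarged_only_up", "enlarged_only_down",
            "reduced_only_up", "reduced_only_down", "unclassified")
  cat_counts <- table(factor(tab$category[tab$significant], levels = cats))

  summary <- list(
    n_sites_input = nrow(tab),
    n_omitted_error = sum(tab$fit_status == "omitted_error"),
    n_omitted_insufficient = sum(tab$fit_status == "omitted_insufficient"),
    n_tested = sum(tested),
    dispersion_hdi = unname(hd$interval),
    n_removed_by_hdi = sum(tested) - sum(tab$kept_by_hdi),
    n_in_fdr_universe = universe,
    n_significant = sum(tab$significant),
    category_counts = as.list(cat_counts)
  )
  list(table = tab, posthoc = ph, summary = summary)
}

#' Manhattan-style diagnostic plot
#'
#' -log10 of the per-site likelihood-ratio p-values against genomic
#' position, with significant sites highlighted and the largest
#' just-significant q-value marked. Base graphics; intended as a quick
#' diagnostic, not a publication figure.
#'
#' @param dms_table the `table` element of [run_dms_pipeline()].
#' @param fdr the q-value threshold used for highlighting.
#' @export
plot_manhattan <- function(dms_table, fdr = 0.05) {
  ok <- is.finite(dms_table$lrt_p)
  tab <- dms_table[ok, , drop = FALSE]
  chr <- factor(tab$chrom, levels = unique(tab$chrom))
  offs <- c(0, cumsum(tapply(tab$pos, chr, max)))[as.integer(chr)]
  xpos <- offs + tab$pos
  col <- ifelse(tab$significant, "darkblue",
                c("grey40", "grey70")[1 + as.integer(chr) %% 2])
  graphics::plot(xpos, -log10(pmax(tab$lrt_p, 1e-300)), pch = 20, col = col,
                 xlab = "genomic position", ylab = expression(-log[10](p)),
                 main = sprintf("%d of %d sites significant at q <= %.2g",
                                sum(tab$significant), nrow(tab), fdr))
  if (any(tab$significant)) {
    thr <- max(tab$lrt_p[tab$significant])
    graphics::abline(h = -log10(thr), col = "red", lty = 3)
  }
  invisible(NULL)
}
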