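#' Filtering thresholds for CpG matrices
#'
#' Defaults follow the study's four rules: discard cells covered below 10x
#' or above the sample's 99.9th coverage percentile, keep sites covered in
#' at least 15 individuals per treatment, and drop sites whose mean
#' methylation across individuals is below 0.05 or above 0.95. All bounds
#' are strict inequalities.
#'
#' @param min_coverage minimum reads per cell (cells below are set missing).
#' @param coverage_percentile_cut upper percentile (per sample) above which
#'   cells are set missing; 100 disables the upper cut.
#' @param min_individuals_per_group minimum covered individuals required in
#'   each treatment.
#' @param mean_meth_low,mean_meth_high retained mean-methylation band.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 10,
                          coverage_percentile_cut = 99.9,
                          min_individuals_per_group = 15,
                          mean_meth_low = 0.05,
                          mean_meth_high = 0.95) {
  stopifnot(min_coverage >= 1,
            coverage_percentile_cut > 0, coverage_percentile_cut <= 100,
            mean_meth_low > 0, mean_meth_low < mean_meth_high,
            mean_meth_high < 1, min_individuals_per_group >= 0)
  structure(list(min_coverage = min_coverage,
                 coverage_percentile_cut = coverage_percentile_cut,
                 min_individuals_per_group = min_individuals_per_group,
                 mean_meth_low = mean_meth_low,
                 mean_meth_high = mean_meth_high),
            class = "filter_config")
}

#' Coverage filter
#'
#' Sets cells missing when the total count is below `min_coverage` or
#' strictly above the sample's own upper coverage percentile. The
#' percentile is the inverse-ECDF (type 1) quantile of that sample's
#' non-missing totals, so the cut is an observed coverage value.
#'
#' @param x a [meth_matrix].
#' @param config a [filter_config()].
#' @return filtered [meth_matrix].
#' @export
filter_by_coverage <- function(x, config = filter_config()) {
  validate_meth_matrix(x)
  for (j in seq_along(x$samples)) {
    tj <- x$total[, j]
    drop <- !is.na(tj) & tj < config$min_coverage
    if (config$coverage_percentile_cut < 100 && any(!is.na(tj))) {
      srt <- sort(tj[!is.na(tj)])
      # inverse-ECDF order statistic, guarded against representation error
      k <- min(length(srt),
               ceiling(length(srt) * config$coverage_percentile_cut / 100 -
                         1e-9))
      drop <- drop | (!is.na(tj) & tj > srt[max(1, k)])
    }
    x$meth[drop, j] <- NA_integer_
    x$total[drop, j] <- NA_integer_
  }
  x
}

#' Group-presence filter
#'
#' Keeps a site only if it has at least `min_individuals_per_group`
#' non-missing cells in the reduced treatment and in the enlarged
#' treatment.
#'
#' @param x a [meth_matrix].
#' @param design data.frame mapping `bird_id` to `treatment`.
#' @param config a [filter_config()].
#' @return filtered [meth_matrix].
#' @export
filter_by_group_presence <- function(x, design, config = filter_config()) {
  validate_meth_matrix(x)
  tr <- design$treatment[match(x$samples, design$bird_id)]
  if (anyNA(tr)) stop("samples missing from design: ",
                      paste(x$samples[is.na(tr)], collapse = ", "))
  covered <- !is.na(x$total)
  n_red <- rowSums(covered[, tr == "reduced", drop = FALSE])
  n_enl <- rowSums(covered[, tr == "enlarged", drop = FALSE])
  keep <- n_red >= config$min_individuals_per_group &
    n_enl >= config$min_individuals_per_group
  x[keep, ]
}

#' Mean-methylation filter
#'
#' Removes sites whose mean per-individual methylation fraction (over
#' non-missing cells) lies strictly below `mean_meth_low` or strictly
#' above `mean_meth_high`. Sites with no covered cells are removed and
#' counted separately.
#'
#' @param x a [meth_matrix].
#' @param config a [filter_config()].
#' @return filtered [meth_matrix]; attribute `n_all_missing` records how
#'   many removed sites had no data at all.
#' @export
filter_by_mean_methylation <- function(x, config = filter_config()) {
  validate_meth_matrix(x)
  frac <- x$meth / x$total
  mm <- rowMeans(frac, na.rm = TRUE)
  all_missing <- !is.finite(mm)
  keep <- !all_missing & mm >= config$mean_meth_low & mm <= config$mean_meth_high
  out <- x[keep, ]
  attr(out, "n_all_missing") <- sum(all_missing)
  out
}

#' Run the full filter pipeline
#'
#' Applies, in order: the per-cell coverage filter (sites left with no
#' covered cell are dropped), the per-treatment presence filter, and the
#' mean-methylation filter. Returns the filtered matrix together with a
#' telescoping report (sites in, removed, out at each stage).
#'
#' @param x a [meth_matrix].
#' @param design design table with `bird_id` and `treatment`.
#' @param config a [filter_config()].
#' @return list with `matrix` and `report` (class `filter_report`).
#' @export
run_filter_pipeline <- function(x, design, config = filter_config()) {
  n0 <- nrow(x$sites)
  x1 <- filter_by_coverage(x, config)
  x1 <- x1[rowSums(!is.na(x1$total)) > 0, ]
  n1 <- nrow(x1$sites)
  x2 <- filter_by_group_presence(x1, design, config)
  n2 <- nrow(x2$sites)
  x3 <- filter_by_mean_methylation(x2, config)
  n3 <- nrow(x3$sites)
  report <- data.frame(
    stage = c("coverage", "group_presence", "mean_methylation"),
    sites_in = c(n0, n1, n2),
    sites_removed = c(n0 - n1, n1 - n2, n2 - n3),
    sites_out = c(n1, n2, n3)
  )
  class(report) <- c("filter_report", "data.frame")
  attr(report, "n_all_missing_at_mean_stage") <- attr(x3, "n_all_missing")
  list(matrix = x3, report = report)
}
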