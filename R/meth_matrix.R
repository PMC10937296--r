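#' Site-by-individual methylation count matrix
#'
#' Container for destranded CpG counts: parallel integer matrices of
#' methylated and total read counts, rows indexed by CpG site (chromosome +
#' 1-based position of the plus-strand cytosine), columns by sample id.
#' Missing cells (site not covered in a sample, or removed by filtering)
#' are `NA` in both matrices, never zero.
#'
#' @param sites data.frame with columns `chrom`, `pos`.
#' @param samples character vector of sample ids.
#' @param meth,total integer matrices, `nrow(sites)` x `length(samples)`.
#' @return object of class `meth_matrix`.
#' @export
meth_matrix <- function(sites, samples, meth, total) {
  obj <- structure(list(sites = sites, samples = as.character(samples),
                        meth = meth, total = total),
                   class = "meth_matrix")
  validate_meth_matrix(obj)
  obj
}

validate_meth_matrix <- function(x) {
  stopifnot(inherits(x, "meth_matrix"),
            all(c("chrom", "pos") %in% names(x$sites)))
  if (any(x$sites$pos < 1)) stop("site positions must be >= 1")
  key <- paste(x$sites$chrom, x$sites$pos)
  if (anyDuplicated(key)) stop("duplicate sites in matrix")
  if (anyDuplicated(x$samples)) stop("duplicate sample ids in matrix")
  if (!all(dim(x$meth) == c(nrow(x$sites), length(x$samples))) ||
      !all(dim(x$total) == dim(x$meth)))
    stop("matrix dimensions inconsistent with sites/samples")
  if (!identical(is.na(x$meth), is.na(x$total)))
    stop("meth and total must share the same missing cells")
  bad <- which(!is.na(x$meth) & (x$meth < 0 | x$total < 0 | x$meth > x$total))
  if (length(bad)) stop("invalid counts: need 0 <= meth <= total in every cell")
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' @method print meth_matrix
#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples (%.1f%% cells covered)\n",
              nrow(x$sites), length(x$samples),
              100 * mean(!is.na(x$total))))
  invisible(x)
}

#' Subset a methylation matrix
#'
#' @param x a [meth_matrix].
#' @param i site index (integer or logical).
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.meth_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  meth_matrix(x$sites[i, , drop = FALSE], x$samples[j],
              x$meth[i, j, drop = FALSE], x$total[i, j, drop = FALSE])
}

site_keys <- function(x) paste(x$sites$chrom, x$sites$pos, sep = ":")
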