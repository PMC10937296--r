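#' Read per-sample CpG counts
#'
#' Parses one sample's methylation calls. Two per-sample dialects are
#' supported: Bismark "coverage" files
#' (`chrom start end pct_methylation count_methylated count_unmethylated`,
#' already destranded, position = start) and Bismark cytosine reports
#' (`chrom pos strand count_methylated count_unmethylated context
#' trinucleotide`), from which only CpG-context rows are kept. A wide
#' multi-sample matrix TSV is read via [read_meth_matrix()] and returned
#' as a `meth_matrix`. Plain or gzip-compressed files are accepted.
#'
#' @param path file path.
#' @param format one of `"coverage"`, `"cytosine_report"`, `"matrix_tsv"`.
#' @return data.frame of records (`chrom`, `pos`, `strand` where present,
#'   `meth`, `total`), or a [meth_matrix] for `"matrix_tsv"`.
#' @export
read_sample_counts <- function(path,
                               format = c("coverage", "cytosine_report",
                                          "matrix_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix_tsv") return(read_meth_matrix(path))

  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty input file: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t| +")
  need <- if (format == "coverage") 6L else 7L
  nf <- lengths(fields)
  if (any(nf < need))
    stop("malformed ", format, " line ", which(nf < need)[1], " in ", path,
         ": expected ", need, " fields")

  get <- function(k) vapply(fields, `[[`, "", k)
  if (format == "coverage") {
    rec <- data.frame(chrom = get(1), pos = as.integer(get(2)),
                      meth = as.integer(get(5)),
                      total = as.integer(get(5)) + as.integer(get(6)),
                      stringsAsFactors = FALSE)
  } else {
    ctx <- get(6)
    keep <- ctx %in% c("CG", "CpG")   # methylation calling in CpG context only
    rec <- data.frame(chrom = get(1)[keep], pos = as.integer(get(2)[keep]),
                      strand = get(3)[keep],
                      meth = as.integer(get(4)[keep]),
                      total = as.integer(get(4)[keep]) + as.integer(get(5)[keep]),
                      stringsAsFactors = FALSE)
    if (any(!rec$strand %in% c("+", "-")))
      stop("invalid strand in ", path)
  }
  if (anyNA(rec$pos) || anyNA(rec$meth) || anyNA(rec$total))
    stop("non-numeric coordinate or count field in ", path)
  if (any(rec$meth < 0) || any(rec$total < rec$meth))
    stop("negative or inconsistent counts in ", path)
  rec
}

#' Merge complementary CpG strands
#'
#' Sums the counts of a plus-strand cytosine at position p with its
#' complementary minus-strand cytosine at p + 1 into a single CpG record
#' anchored at p. A lone minus-strand record is re-anchored to p - 1.
#' Records without a strand column are assumed destranded and passed
#' through unchanged.
#'
#' @param records data.frame from [read_sample_counts()].
#' @return destranded data.frame (`chrom`, `pos`, `meth`, `total`).
#' @export
merge_complementary_strands <- function(records) {
  if (!"strand" %in% names(records)) return(records)
  anchor <- ifelse(records$strand == "-", records$pos - 1L, records$pos)
  if (anyDuplicated(paste(records$chrom, records$pos, records$strand)))
    stop("duplicate records at the same position and strand")
  key <- paste(records$chrom, anchor, sep = ":")
  meth <- rowsum(records$meth, key)
  total <- rowsum(records$total, key)
  first <- !duplicated(key)
  out <- data.frame(chrom = records$chrom[first], pos = anchor[first],
                    meth = meth[unique(key), 1], total = total[unique(key), 1],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Assemble a site-by-individual matrix from per-sample records
#'
#' Takes the union of sites across samples; cells absent in a sample are
#' marked missing, never zero-filled.
#'
#' @param samples named list of destranded record data.frames (names are
#'   sample ids).
#' @return a [meth_matrix].
#' @export
assemble_matrix <- function(samples) {
  if (length(samples) == 0) stop("need at least one sample")
  ids <- names(samples)
  if (is.null(ids) || any(!nzchar(ids))) stop("samples must be a named list")
  if (anyDuplicated(ids)) stop("duplicate sample id: ",
                               ids[duplicated(ids)][1])
  allsites <- unique(do.call(rbind, lapply(samples, function(r)
    r[, c("chrom", "pos"), drop = FALSE])))
  allsites <- allsites[order(allsites$chrom, allsites$pos), , drop = FALSE]
  rownames(allsites) <- NULL
  key <- paste(allsites$chrom, allsites$pos, sep = ":")
  meth <- tot <- matrix(NA_integer_, nrow(allsites), length(ids),
                        dimnames = list(NULL, ids))
  for (j in seq_along(samples)) {
    r <- samples[[j]]
    i <- match(paste(r$chrom, r$pos, sep = ":"), key)
    meth[i, j] <- r$meth
    tot[i, j] <- r$total
  }
  meth_matrix(allsites, ids, meth, tot)
}

#' Write / read a wide methylation matrix TSV
#'
#' Columns `chrom`, `pos`, then `<sample>.meth` and `<sample>.total` per
#' sample; missing cells are `NA`.
#'
#' @param x a [meth_matrix].
#' @param path output/input file.
#' @return `read_meth_matrix` returns a [meth_matrix]; the writer returns
#'   `path` invisibly.
#' @export
write_meth_matrix <- function(x, path) {
  validate_meth_matrix(x)
  wide <- x$sites
  for (j in seq_along(x$samples)) {
    wide[[paste0(x$samples[j], ".meth")]] <- x$meth[, j]
    wide[[paste0(x$samples[j], ".total")]] <- x$total[, j]
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  wide <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  mcols <- grep("\\.meth$", names(wide), value = TRUE)
  ids <- sub("\\.meth$", "", mcols)
  meth <- as.matrix(wide[, paste0(ids, ".meth"), drop = FALSE])
  tot <- as.matrix(wide[, paste0(ids, ".total"), drop = FALSE])
  dimnames(meth) <- dimnames(tot) <- list(NULL, ids)
  meth_matrix(wide[, c("chrom", "pos")], ids, meth, tot)
}

#' Write per-sample Bismark-coverage-style files
#'
#' One file per sample (`<id>.cov`) with columns chrom, start, end,
#' percent methylation, methylated count, unmethylated count; missing cells
#' are skipped.
#'
#' @param x a [meth_matrix].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_coverage_files <- function(x, dir) {
  validate_meth_matrix(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(x$samples))
  for (j in seq_along(x$samples)) {
    keep <- !is.na(x$total[, j]) & x$total[, j] > 0
    df <- data.frame(x$sites$chrom[keep], x$sites$pos[keep], x$sites$pos[keep],
                     round(100 * x$meth[keep, j] / x$total[keep, j], 2),
                     x$meth[keep, j], x$total[keep, j] - x$meth[keep, j])
    paths[j] <- file.path(dir, paste0(x$samples[j], ".cov"))
    write.table(df, paths[j], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Write retained sites as BED
#'
#' Output intervals are 0-based half-open around the 1-based plus-strand
#' cytosine anchor.
#'
#' @param sites data.frame with `chrom`, `pos` and optionally `name`.
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  name <- if ("name" %in% names(sites)) sites$name else "."
  bed <- data.frame(sites$chrom, sites$pos - 1L, sites$pos, name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
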