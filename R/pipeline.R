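#' Run the full analysis pipeline
#'
#' Composes the stages — filtering, per-CpG screening, annotation and
#' (when a phenotype table is given) the phenotype mixed-model stage —
#' from a single configuration, writing every stage output plus a summary
#' JSON and a log (seed, config hash) into a run directory.
#'
#' @param config named list, or path to a YAML/JSON file, with elements:
#'   `matrix` (wide matrix TSV) or `coverage_dir` (directory of per-sample
#'   `.cov` files), `design` (TSV), optional `phenotypes` (TSV), optional
#'   `gff3`, `outdir`, optional `seed`, plus optional sub-lists `filter`,
#'   `dms` and `annotation` overriding [filter_config()],
#'   [run_dms_pipeline()] and [annotation_config()] arguments.
#' @return the run directory path, invisibly; stage outputs live in it
#'   (`filtered_matrix.tsv`, `filter_report.tsv`, `dms_table.tsv`,
#'   `dms_significant.bed`, `annotated_dms.tsv`, `phenotypes_*.tsv`,
#'   `summary.json`, `run.log`).
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  stage <- "load"
  res <- tryCatch({
    for (p in c("matrix", "design", "phenotypes", "gff3"))
      if (!is.null(config[[p]]) && !file.exists(config[[p]]))
        stop("input path for '", p, "' does not exist: ", config[[p]])

    mat <- if (!is.null(config$matrix)) {
      read_meth_matrix(config$matrix)
    } else if (!is.null(config$coverage_dir)) {
      files <- list.files(config$coverage_dir, "\\.cov(\\.gz)?$",
                          full.names = TRUE)
      if (length(files) == 0) stop("no .cov files in ", config$coverage_dir)
      recs <- lapply(files, read_sample_counts, format = "coverage")
      names(recs) <- sub("\\.cov(\\.gz)?$", "", basename(files))
      assemble_matrix(recs)
    } else stop("config needs 'matrix' or 'coverage_dir'")
    design <- read.table(config$design, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
    design$treatment <- factor(design$treatment,
                               levels = c("reduced", "enlarged"))

    stage <- "filter"
    fcfg <- do.call(filter_config, config$filter %||% list())
    filt <- run_filter_pipeline(mat, design, fcfg)
    write_meth_matrix(filt$matrix, file.path(outdir, "filtered_matrix.tsv"))
    write.table(filt$report, file.path(outdir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "dms"
    set.seed(seed)
    dms <- do.call(run_dms_pipeline,
                   c(list(x = filt$matrix, design = design),
                     config$dms %||% list()))
    write.table(dms$table, file.path(outdir, "dms_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- dms$table[dms$table$significant, c("chrom", "pos")]
    sig$name <- dms$table$category[dms$table$significant]
    names(sig)[3] <- "name"
    write_sites_bed(sig, file.path(outdir, "dms_significant.bed"))

    ann_counts <- NULL
    if (!is.null(config$gff3)) {
      stage <- "annotate"
      acfg <- do.call(annotation_config, config$annotation %||% list())
      index <- load_gene_models(config$gff3, acfg)
      ann <- annotate_table(dms$table[dms$table$significant, , drop = FALSE],
                            index)
      write.table(ann$table, file.path(outdir, "annotated_dms.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ann_counts <- as.list(ann$class_counts)
    }

    pheno_summary <- NULL
    if (!is.null(config$phenotypes)) {
      stage <- "phenotypes"
      ptab <- read.table(config$phenotypes, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
      pres <- analyze_phenotypes(ptab)
      for (nm in names(pres)) {
        write.table(cbind(term = rownames(pres[[nm]]$anova),
                          pres[[nm]]$anova),
                    file.path(outdir, paste0("phenotypes_", nm, "_anova.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(pres[[nm]]$slopes))
          write.table(pres[[nm]]$slopes,
                      file.path(outdir, paste0("phenotypes_", nm, "_slopes.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
      }
      pheno_summary <- lapply(pres, function(r)
        list(final_terms = r$final_terms))
    }

    summary <- list(
      filter = list(report = filt$report,
                    n_sites_retained = nrow(filt$matrix$sites)),
      dms = dms$summary,
      annotation_class_counts = ann_counts,
      phenotypes = pheno_summary,
      n_dms_table_rows = nrow(dms$table)
    )
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_file <- file.path(outdir, "config_used.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  log <- c(
    paste("run:", format(Sys.time())),
    paste("package version:", as.character(utils::packageVersion("broodmethyl"))),
    paste("seed:", seed),
    paste("config md5:", unname(tools::md5sum(cfg_file)))
  )
  writeLines(log, file.path(outdir, "run.log"))
  invisible(outdir)
}
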