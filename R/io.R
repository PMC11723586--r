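#' Standard-format I/O and pipeline orchestration
#'
#' Count-matrix readers and writers (TSV and MatrixMarket with name
#' sidecars), sample-table I/O, a flat YAML pipeline configuration and the
#' end-to-end pipeline driver.  The package's functions are the primary
#' interface; `run_pipeline()` chains them for a one-call analysis.
#'
#' @name io
NULL

#' Read a count matrix with sample metadata
#'
#' TSV format: genes in rows (first column = gene IDs), samples in
#' columns.  MatrixMarket format: `path` plus sidecar files
#' `<path>.rownames` and `<path>.colnames` (one name per line).  Counts
#' are validated as non-negative integers and sample IDs matched against
#' the metadata's `sample_id` column.
#'
#' @param path Counts file path.
#' @param samples_path Sample-metadata TSV path (needs `sample_id`).
#' @param format `"tsv"` or `"mtx"`.
#' @return List with `counts` (integer matrix, genes x samples),
#'   `samples` (data frame aligned to columns) and `library_sizes`.
#' @export
read_counts <- function(path, samples_path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    counts <- as.matrix(df)
  } else {
    counts <- as.matrix(Matrix::readMM(path))
    rownames(counts) <- readLines(paste0(path, ".rownames"))
    colnames(counts) <- readLines(paste0(path, ".colnames"))
  }
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative counts at e.g. gene '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "integer"
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(samples)) {
    stop("sample metadata must have a 'sample_id' column")
  }
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  missing_counts <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_meta) || length(missing_counts)) {
    stop("sample ID mismatch; missing from metadata: ",
         paste(missing_meta, collapse = ", "),
         "; missing from counts: ",
         paste(missing_counts, collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  rownames(samples) <- samples$sample_id
  list(counts = counts, samples = samples,
       library_sizes = colSums(counts))
}

#' Write a count matrix
#'
#' @param counts Genes x samples matrix.
#' @param path Output path.
#' @param format `"tsv"` (gene IDs in the first column) or `"mtx"`
#'   (MatrixMarket plus `.rownames`/`.colnames` sidecars).
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Write a result table with provenance header comments
#'
#' @param df Data frame.
#' @param path Output TSV path.
#' @param provenance Named character vector written as `# key=value`
#'   comment lines.
#' @export
write_result_table <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param output_dir Directory for result tables (NULL keeps results in
#'   memory only).
#' @param counts_path,samples_path Input files (NULL simulates instead).
#' @param lrp_path Ligand-receptor TSV (NULL skips the interactome stage).
#' @param gmt_path GMT collection (NULL skips the enrichment stage).
#' @param junction_genes Gene list for the joint location-scale screen
#'   (NULL skips it).
#' @param lineage_p,lineage_lfc Lineage-specificity thresholds (0.001, 1).
#' @param age_p Age-significance threshold (0.05).
#' @param de_fold,dv_fold Attribution fold thresholds (2, 2).
#' @param sim_config Simulation configuration when no counts are given.
#' @param seed Pipeline seed.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = NULL, counts_path = NULL,
                            samples_path = NULL, lrp_path = NULL,
                            gmt_path = NULL, junction_genes = NULL,
                            lineage_p = 0.001, lineage_lfc = 1,
                            age_p = 0.05, de_fold = 2, dv_fold = 2,
                            sim_config = default_config(), seed = 42) {
  structure(list(output_dir = output_dir, counts_path = counts_path,
                 samples_path = samples_path, lrp_path = lrp_path,
                 gmt_path = gmt_path, junction_genes = junction_genes,
                 lineage_p = lineage_p, lineage_lfc = lineage_lfc,
                 age_p = age_p, de_fold = de_fold, dv_fold = dv_fold,
                 sim_config = sim_config, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Scalar keys override the [pipeline_config()] defaults; keys under
#' `sim_config` override the simulation defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  sim_over <- vals$sim_config
  vals$sim_config <- NULL
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  for (k in names(sim_over)) cfg$sim_config[[k]] <- sim_over[[k]]
  cfg
}

#' Run the lineage-fidelity pipeline end to end
#'
#' Stages: load or simulate counts; expression filter; normalization and
#' batch adjustment; four DE contrasts; DV per lineage; strata, shift
#' statistics, attribution and direction summaries; optional interactome,
#' joint location-scale screen and enrichment stages.  Every stage's
#' output is returned (and written as TSV when `output_dir` is set); a
#' rerun with the same configuration is bit-identical for deterministic
#' stages.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "),
                                   "[pipeline] ", ...)
  out <- list(config = config)

  if (!is.null(config$counts_path)) {
    log_msg("reading counts from ", config$counts_path)
    dat <- read_counts(config$counts_path, config$samples_path)
    dat$truth <- NULL
  } else {
    log_msg("simulating dataset (seed ", config$sim_config$seed, ")")
    dat <- simulate_dataset(config$sim_config)
    out$truth <- dat$truth
  }
  counts <- dat$counts; samples <- dat$samples

  keep <- filter_expressed(counts, samples, min_count = 5,
                           min_fraction = 0.5)
  log_msg(length(keep), " of ", nrow(counts), " genes pass expression filter")
  counts <- counts[keep, , drop = FALSE]

  sf <- size_factors(counts)
  expr <- log_transform(counts, sf)
  expr <- adjust_batch(expr, samples)
  agg <- aggregate_subjects(expr, samples)
  out$expr_subject <- agg$expr
  out$samples_subject <- agg$samples

  log_msg("running 4 DE contrasts")
  out$de <- list(
    MEPvsLEP_young = run_de(counts, samples, "MEPvsLEP_young"),
    MEPvsLEP_old   = run_de(counts, samples, "MEPvsLEP_old"),
    OldvsYoung_LEP = run_de(counts, samples, "OldvsYoung_LEP"),
    OldvsYoung_MEP = run_de(counts, samples, "OldvsYoung_MEP"))

  log_msg("running DV per lineage")
  out$dv <- list(LEP = dv_test(counts, samples, "LEP"),
                 MEP = dv_test(counts, samples, "MEP"))
  out$varratio <- list(
    LEP = variance_ratio(agg$expr, agg$samples, "LEP"),
    MEP = variance_ratio(agg$expr, agg$samples, "MEP"))

  log_msg("building strata and fidelity report")
  out$strata <- build_strata(out$de$MEPvsLEP_young, out$de$MEPvsLEP_old,
                             config$lineage_p, config$lineage_lfc)
  spec_young <- classify_specificity(out$de$MEPvsLEP_young,
                                     config$lineage_p, config$lineage_lfc)
  out$shift <- lapply(c(LEP = "LEP", MEP = "MEP"), function(cl) {
    genes <- names(spec_young)[spec_young == cl]
    if (length(genes) < 3L) return(NULL)
    lfc_shift_report(out$de$MEPvsLEP_young, out$de$MEPvsLEP_old, genes)
  })
  out$attribution <- attribute_loss(
    out$strata, out$de$OldvsYoung_LEP, out$de$OldvsYoung_MEP,
    out$varratio$LEP, out$varratio$MEP,
    p_sig = config$age_p, de_fold = config$de_fold,
    dv_fold = config$dv_fold)
  out$direction <- list(
    LEP = direction_summary(out$de$OldvsYoung_LEP, out$de$MEPvsLEP_young,
                            "LEP", config$age_p),
    MEP = direction_summary(out$de$OldvsYoung_MEP, out$de$MEPvsLEP_young,
                            "MEP", config$age_p))

  if (!is.null(config$lrp_path) && file.exists(config$lrp_path)) {
    log_msg("interactome stage")
    lrp <- load_lrp_table(config$lrp_path)
    calls <- call_lineage_lrps(lrp, out$de$MEPvsLEP_young,
                               config$lineage_p, config$lineage_lfc)
    out$lrp <- find_disrupted_lrps(calls, out$de$MEPvsLEP_old,
                                   config$lineage_p, config$lineage_lfc)
  } else {
    log_msg("no LRP table; interactome stage skipped")
  }

  if (!is.null(config$junction_genes)) {
    log_msg("joint location-scale screen")
    genes <- intersect(config$junction_genes, rownames(agg$expr))
    out$lepage_screen <- lapply(c(LEP = "LEP", MEP = "MEP"), function(ln) {
      sel <- agg$samples$lineage == ln
      ag <- agg$samples$age[sel]
      res <- lapply(genes, function(g) {
        v <- agg$expr[g, sel]
        lt <- suppressWarnings(lepage_test(v[ag == "young"], v[ag == "old"],
                                           seed = config$seed))
        data.frame(gene = g, L = lt$statistic, p = lt$p_value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    })
  }

  if (!is.null(config$gmt_path) && file.exists(config$gmt_path)) {
    log_msg("enrichment stage on age-DE rank statistics")
    sets <- read_gmt(config$gmt_path)
    stats_vec <- stats::setNames(out$de$OldvsYoung_LEP$t,
                                 out$de$OldvsYoung_LEP$gene)
    out$gsea <- preranked_gsea(stats_vec, sets, n_perm = 1000,
                               seed = config$seed)
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- c(seed = as.character(config$seed),
              package = as.character(utils::packageVersion("epifidelity")))
    for (nm in names(out$de)) {
      write_result_table(out$de[[nm]],
                         file.path(config$output_dir,
                                   paste0("de_", nm, ".tsv")), prov)
    }
    for (nm in names(out$dv)) {
      write_result_table(out$dv[[nm]],
                         file.path(config$output_dir,
                                   paste0("dv_", nm, ".tsv")), prov)
    }
    write_result_table(out$strata$table,
                       file.path(config$output_dir, "strata.tsv"), prov)
    summary_df <- data.frame(
      metric = c("n_lost", "via_sig_DE", "via_2fold_DE", "via_2fold_DV",
                 "overlap", "unexplained"),
      value = unlist(out$attribution, use.names = FALSE))
    write_result_table(summary_df,
                       file.path(config$output_dir, "attribution.tsv"),
                       prov)
    if (!is.null(out$lrp)) {
      write_result_table(out$lrp,
                         file.path(config$output_dir, "lrp_calls.tsv"),
                         prov)
    }
  }
  log_msg("done in ", round(as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")), 1), " s")
  out
}
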