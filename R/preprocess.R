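#' Normalization, batch adjustment and expression-matrix utilities
#'
#' Median-of-ratios size factors, log transformation, design-preserving
#' batch adjustment, replicate aggregation to subject level, expression
#' filtering, cross-dataset concordance checks, quantile-category shift
#' matrices and hierarchical sample clustering.
#'
#' @name preprocess
NULL

# Light-weight provenance wrapper: a plain numeric matrix with flags.
expr_matrix <- function(x, normalized = FALSE, batch_adjusted = FALSE,
                        subject_level = FALSE, size_factors = NULL) {
  attr(x, "normalized") <- normalized
  attr(x, "batch_adjusted") <- batch_adjusted
  attr(x, "subject_level") <- subject_level
  attr(x, "size_factors") <- size_factors
  x
}

#' Median-of-ratios size factors
#'
#' Per-gene geometric-mean reference over samples (genes with any zero
#' count are excluded from the reference); a sample's factor is the median
#' of its ratios to the reference.  When no gene is non-zero in every
#' sample, falls back to total-count scaling centred to geometric mean 1,
#' with a warning.
#'
#' @param counts Genes x samples count matrix.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) {
    warning("no gene has nonzero counts in every sample; using total-count scaling")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  logref <- rowMeans(log(counts[keep, , drop = FALSE]))
  sf <- apply(counts[keep, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - logref))
  })
  unname(sf)
}

#' Log2 transform of normalized counts
#'
#' value = log2(count / factor + pseudocount).  A stand-in for shrinkage
#' log transforms: downstream statistics require only an approximately
#' variance-stabilized log scale.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample positive size factors (default
#'   [size_factors()] of `counts`).
#' @param pseudocount Added inside the log (default 1).
#' @return An expression matrix (log2 scale) carrying provenance flags.
#' @export
log_transform <- function(counts, factors = size_factors(counts),
                          pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(factors <= 0) || length(factors) != ncol(counts)) {
    stop("size factors must be positive, one per sample")
  }
  x <- log2(sweep(counts, 2L, factors, "/") + pseudocount)
  expr_matrix(x, normalized = TRUE, size_factors = factors)
}

#' Remove additive batch effects while preserving the biological design
#'
#' Fits, per gene, an additive linear model containing the lineage-by-age
#' design plus batch indicators and subtracts the fitted batch terms
#' (reference-batch centred), leaving the biological coefficients unchanged
#' in expectation.  Optionally equalizes residual standard deviations
#' across batches.
#'
#' @param expr Log-scale expression matrix (genes x samples).
#' @param samples Sample table with `lineage`, `age` and `batch` columns
#'   aligned to the expression columns.
#' @param scale_adjust Also equalize per-batch residual SDs (default FALSE).
#' @return Batch-adjusted expression matrix.
#' @export
adjust_batch <- function(expr, samples, scale_adjust = FALSE) {
  stopifnot(ncol(expr) == nrow(samples))
  batch <- factor(samples$batch)
  if (nlevels(batch) < 2L) return(expr_matrix(as.matrix(expr) + 0,
    normalized = isTRUE(attr(expr, "normalized")), batch_adjusted = TRUE,
    subject_level = isTRUE(attr(expr, "subject_level")),
    size_factors = attr(expr, "size_factors")))
  group <- factor(paste(samples$lineage, samples$age, sep = "_"))
  design <- stats::model.matrix(~group)
  full <- cbind(design, stats::model.matrix(~batch)[, -1, drop = FALSE])
  if (qr(full)$rank < ncol(full)) {
    stop("batch is confounded with the lineage-by-age design; cannot adjust")
  }
  out <- limma::removeBatchEffect(as.matrix(expr), batch = batch,
                                  design = design)
  if (scale_adjust) {
    fit <- stats::lm.fit(full, t(out))
    res <- t(fit$residuals)
    for (b in levels(batch)) {
      idx <- which(batch == b)
      sd_b <- sqrt(rowMeans(res[, idx, drop = FALSE]^2))
      sd_all <- sqrt(rowMeans(res^2))
      ratio <- ifelse(sd_b > 0, sd_all / sd_b, 1)
      fitted_b <- out[, idx, drop = FALSE] - res[, idx, drop = FALSE]
      out[, idx] <- fitted_b + res[, idx, drop = FALSE] * ratio
    }
  }
  expr_matrix(out, normalized = isTRUE(attr(expr, "normalized")),
              batch_adjusted = TRUE,
              subject_level = isTRUE(attr(expr, "subject_level")),
              size_factors = attr(expr, "size_factors"))
}

#' Average sample replicates to subject level
#'
#' Arithmetic mean over sample replicates within each subject-by-lineage
#' cell; idempotent on subject-level input.
#'
#' @param expr Expression matrix (genes x samples).
#' @param samples Sample table with `subject` and `lineage` columns.
#' @return List with `expr` (genes x subject-lineage cells) and `samples`
#'   (one row per cell: subject, lineage, age, batch).
#' @export
aggregate_subjects <- function(expr, samples) {
  stopifnot(ncol(expr) == nrow(samples))
  key <- paste(samples$subject, samples$lineage, sep = ".")
  ukey <- unique(key)
  out <- vapply(ukey, function(k) {
    rowMeans(as.matrix(expr)[, key == k, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr))
  dimnames(out) <- list(rownames(expr), ukey)
  meta <- samples[match(ukey, key),
                  intersect(c("subject", "lineage", "age", "batch"),
                            colnames(samples)), drop = FALSE]
  meta$sample_id <- ukey
  rownames(meta) <- ukey
  list(expr = expr_matrix(out,
                          normalized = isTRUE(attr(expr, "normalized")),
                          batch_adjusted = isTRUE(attr(expr, "batch_adjusted")),
                          subject_level = TRUE,
                          size_factors = NULL),
       samples = meta)
}

#' Expression filter by lineage-by-age cell
#'
#' Keeps genes with at least `min_count` in at least `min_fraction` of the
#' samples of at least one lineage-by-age cell.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Sample table with `lineage` and `age` columns.
#' @param min_count Minimum count (default 10).
#' @param min_fraction Minimum within-cell sample fraction (default 0.7).
#' @return Character vector of retained gene names.
#' @export
filter_expressed <- function(counts, samples, min_count = 10,
                             min_fraction = 0.7) {
  stopifnot(min_count >= 0, min_fraction > 0, min_fraction <= 1)
  cellkey <- paste(samples$lineage, samples$age, sep = "_")
  pass <- Reduce(`|`, lapply(unique(cellkey), function(k) {
    sub <- as.matrix(counts)[, cellkey == k, drop = FALSE]
    rowMeans(sub >= min_count) >= min_fraction
  }))
  rownames(counts)[pass]
}

#' Cross-dataset concordance of expression and lineage calls
#'
#' Regresses per-gene mean expression of dataset B on dataset A over the
#' shared gene universe (OLS slope, intercept, R^2) and retains shared
#' genes except those whose lineage log2 fold change flips sign between
#' datasets while both exceed the fold-change threshold.
#'
#' @param exprA,exprB Expression matrices with gene rownames.
#' @param deA,deB Lineage (MEP vs LEP) DE tables with `gene` and `lfc`.
#' @param lfc_thr Fold-change threshold defining a confident sign flip
#'   (default 1).
#' @param r2_min Optional minimum R^2; a lower observed value is reported
#'   with a warning, not an error.
#' @return List: `retained` genes, `slope`, `intercept`, `r2`.
#' @export
concordance_filter <- function(exprA, exprB, deA, deB, lfc_thr = 1,
                               r2_min = NULL) {
  shared <- intersect(rownames(exprA), rownames(exprB))
  if (length(shared) < 10L) stop("fewer than 10 shared genes")
  ma <- rowMeans(as.matrix(exprA)[shared, , drop = FALSE])
  mb <- rowMeans(as.matrix(exprB)[shared, , drop = FALSE])
  fit <- stats::lm(mb ~ ma)
  r2 <- summary(fit)$r.squared
  lfcA <- deA$lfc[match(shared, deA$gene)]
  lfcB <- deB$lfc[match(shared, deB$gene)]
  flip <- !is.na(lfcA) & !is.na(lfcB) &
    sign(lfcA) != sign(lfcB) & abs(lfcA) >= lfc_thr & abs(lfcB) >= lfc_thr
  if (!is.null(r2_min) && r2 < r2_min) {
    warning(sprintf("concordance R^2 = %.3f below requested minimum %.3f",
                    r2, r2_min))
  }
  list(retained = shared[!flip],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2)
}

#' Quantile-category transition matrices between cohorts
#'
#' Computes per-gene means and variances within each cohort, bins them into
#' quantile categories using the younger cohort's quantiles as bin edges,
#' and counts genes by (young bin, old bin) for both moments.
#'
#' @param expr_young,expr_old Subject-level expression matrices for one
#'   lineage (same gene universe).
#' @param n_bins Number of quantile categories (default 4).
#' @return List with `mean_transition` and `variance_transition`
#'   (n_bins x n_bins count matrices; rows = young bin, columns = old bin).
#' @export
quantile_shift <- function(expr_young, expr_old, n_bins = 4) {
  stopifnot(n_bins >= 2, nrow(expr_young) == nrow(expr_old))
  bin_pair <- function(y_stat, o_stat) {
    edges <- stats::quantile(y_stat, probs = seq(0, 1, length.out = n_bins + 1))
    edges <- unique(edges)
    if (length(edges) < n_bins + 1) {
      warning("degenerate young quantiles; merging bins")
    }
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    yb <- cut(y_stat, edges, labels = FALSE)
    ob <- cut(o_stat, edges, labels = FALSE)
    k <- length(edges) - 1L
    tab <- table(factor(yb, levels = seq_len(k)),
                 factor(ob, levels = seq_len(k)))
    m <- matrix(as.integer(tab), k, k,
                dimnames = list(young = paste0("Q", seq_len(k)),
                                old = paste0("Q", seq_len(k))))
    m
  }
  ey <- as.matrix(expr_young); eo <- as.matrix(expr_old)
  list(mean_transition = bin_pair(rowMeans(ey), rowMeans(eo)),
       variance_transition = bin_pair(apply(ey, 1L, stats::var),
                                      apply(eo, 1L, stats::var)))
}

#' Hierarchical clustering of samples
#'
#' Ward (ward.D2) agglomeration on Euclidean distances of per-gene
#' z-scored expression, optionally restricted to a gene subset.  Genes
#' with zero variance are dropped before scaling.
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene_subset Optional character vector of genes to use.
#' @return `hclust` object; leaf order is in `$order`.
#' @export
cluster_samples <- function(expr, gene_subset = NULL) {
  x <- as.matrix(expr)
  if (!is.null(gene_subset)) x <- x[intersect(gene_subset, rownames(x)), ,
                                    drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 samples to cluster")
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  z <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  stats::hclust(stats::dist(t(z)), method = "ward.D2")
}
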