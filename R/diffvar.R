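#' Differential variability between age cohorts
#'
#' Per-gene negative-binomial likelihood-ratio test comparing
#' age-group-specific against shared dispersion (group-specific means in
#' both models), with standardized-residual outlier removal, plus a simple
#' subject-level variance-ratio estimator on transformed values.
#'
#' @name diffvar
NULL

# NB log-likelihood at group-mean MLEs for a given dispersion phi.
nb_loglik <- function(yy, mu, phi) {
  sum(stats::dnbinom(yy, mu = mu, size = 1 / phi, log = TRUE))
}

# 1-D dispersion MLE on log phi; returns list(phi, ll, converged).
# `groups` is a list of numeric count vectors sharing one phi, each with
# its own mean (estimated by the group sample mean).
fit_phi <- function(groups, lo = 1e-6, hi = 1e3) {
  mus <- lapply(groups, mean)
  if (any(unlist(mus) <= 0)) return(list(phi = NA, ll = NA, converged = FALSE))
  nll <- function(logphi) {
    phi <- exp(logphi)
    -sum(mapply(function(yy, mu) nb_loglik(yy, mu, phi), groups, mus))
  }
  opt <- stats::optimize(nll, interval = log(c(lo, hi)))
  list(phi = exp(opt$minimum), ll = -opt$objective, converged = TRUE)
}

#' Negative-binomial dispersion likelihood-ratio test
#'
#' On subject-level normalized counts of one lineage: the full model gives
#' each age group its own NB mean and dispersion, the null model shares one
#' dispersion (means stay group-specific).  LRT = 2 (ll_full - ll_null)
#' against chi-square with 1 df.  Observations with |standardized Pearson
#' residual| beyond `outlier_threshold` under the null fit are removed and
#' the models refit; genes left with fewer than 3 subjects in either group
#' are flagged inestimable.
#'
#' @param counts Genes x samples count matrix (sample level; replicates are
#'   averaged to subject level internally after size-factor normalization).
#' @param samples Sample table with `subject`, `lineage`, `age` columns.
#' @param lineage `"LEP"` or `"MEP"`.
#' @param outlier_threshold Absolute standardized-residual cutoff
#'   (default 4).
#' @return `DVResult` data frame: gene, dv_lfc (log2 phi_old/phi_young),
#'   lrt, p, adj_p, n_outliers_removed, estimable.
#' @export
dv_test <- function(counts, samples, lineage = c("LEP", "MEP"),
                    outlier_threshold = 4) {
  lineage <- match.arg(lineage)
  sel <- samples$lineage == lineage
  if (!any(sel)) stop("lineage absent from sample table")
  counts <- as.matrix(counts)[, sel, drop = FALSE]
  samples <- samples[sel, , drop = FALSE]
  if (min(table(samples$age[!duplicated(samples$subject)])) < 3L) {
    stop("need >= 3 subjects per age group")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  key <- samples$subject
  ukey <- unique(key)
  subj <- vapply(ukey, function(k) {
    rowMeans(norm[, key == k, drop = FALSE])
  }, numeric(nrow(norm)))
  subj <- round(subj)
  age <- samples$age[match(ukey, key)]
  yidx <- which(age == "young"); oidx <- which(age == "old")

  one_gene <- function(yv) {
    y <- yv[yidx]; o <- yv[oidx]
    res <- list(dv_lfc = NA_real_, lrt = NA_real_, p = NA_real_,
                n_out = 0L, estimable = FALSE)
    null0 <- fit_phi(list(y, o))
    if (!null0$converged) return(res)
    # outlier removal under the null fit
    pr <- c((y - mean(y)) / sqrt(mean(y) + null0$phi * mean(y)^2),
            (o - mean(o)) / sqrt(mean(o) + null0$phi * mean(o)^2))
    keep <- abs(pr) <= outlier_threshold
    n_out <- sum(!keep)
    y <- y[keep[seq_along(y)]]
    o <- o[keep[-seq_along(yidx)]]
    res$n_out <- n_out
    if (length(y) < 3L || length(o) < 3L) return(res)
    nul <- fit_phi(list(y, o))
    fy <- fit_phi(list(y))
    fo <- fit_phi(list(o))
    if (!nul$converged || !fy$converged || !fo$converged) return(res)
    lrt <- max(0, 2 * (fy$ll + fo$ll - nul$ll))
    res$dv_lfc <- log2(fo$phi / fy$phi)
    res$lrt <- lrt
    res$p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    res$estimable <- TRUE
    res
  }

  rows <- apply(subj, 1L, one_gene)
  out <- data.frame(
    gene = rownames(counts),
    dv_lfc = vapply(rows, `[[`, 0, "dv_lfc"),
    lrt = vapply(rows, `[[`, 0, "lrt"),
    p = vapply(rows, `[[`, 0, "p"),
    n_outliers_removed = vapply(rows, `[[`, 0L, "n_out"),
    estimable = vapply(rows, `[[`, TRUE, "estimable"),
    stringsAsFactors = FALSE
  )
  out$adj_p <- adjust_pvalues(out$p, "BH")
  rownames(out) <- out$gene
  attr(out, "lineage") <- lineage
  out
}

#' Between-subject variance ratio (old / young)
#'
#' Unbiased sample variances of subject-level log-scale values per age
#' group and their ratio.  By convention the fold is Inf when only the old
#' cohort has positive variance and 1 when both variances are zero.
#'
#' @param expr Subject-level expression matrix (genes x subject-lineage
#'   cells).
#' @param samples Matching table with `lineage` and `age` columns.
#' @param lineage `"LEP"` or `"MEP"`.
#' @return Data frame: gene, var_young, var_old, fold.
#' @export
variance_ratio <- function(expr, samples, lineage = c("LEP", "MEP")) {
  lineage <- match.arg(lineage)
  sel <- samples$lineage == lineage
  if (!any(sel)) stop("lineage absent from sample table")
  x <- as.matrix(expr)[, sel, drop = FALSE]
  age <- samples$age[sel]
  vy <- if (sum(age == "young") >= 2L) {
    apply(x[, age == "young", drop = FALSE], 1L, stats::var)
  } else rep(NA_real_, nrow(x))
  vo <- if (sum(age == "old") >= 2L) {
    apply(x[, age == "old", drop = FALSE], 1L, stats::var)
  } else rep(NA_real_, nrow(x))
  fold <- ifelse(vy > 0, vo / vy, ifelse(vo > 0, Inf, 1))
  data.frame(gene = rownames(x), var_young = vy, var_old = vo,
             fold = fold, row.names = rownames(x),
             stringsAsFactors = FALSE)
}
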