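#' Shared statistical primitives
#'
#' Rank tests, distribution tests, the Lepage joint location-scale test,
#' exact contingency tests, multiple-testing adjustment and standardized
#' mean differences used throughout the lineage-fidelity pipeline.
#'
#' @name stats-core
NULL

# Container for two-sample test output.  `components` carries named
# sub-statistics (e.g. the location and scale Z^2 terms of the Lepage test).
new_test_result <- function(statistic, p_value, method, n1, n2,
                            components = NULL) {
  stopifnot(p_value >= -1e-12, p_value <= 1 + 1e-12)
  structure(
    list(statistic = unname(statistic),
         p_value = min(max(unname(p_value), 0), 1),
         method = method, n1 = n1, n2 = n2,
         components = components),
    class = "fid_test_result"
  )
}

#' @export
print.fid_test_result <- function(x, ...) {
  cat(sprintf("Two-sample test (%s): statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  if (!is.null(x$components)) {
    cat("  components:",
        paste(sprintf("%s = %.4g", names(x$components), x$components),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with cumulative-minimum monotonicity) or
#' Bonferroni adjustment.  Missing values propagate and are excluded from
#' the number of tests.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_pvalues(c(0.01, 0.04, 0.03, 0.002))
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- pvals
  out[ok] <- stats::p.adjust(pvals[ok], method = method)
  out
}

#' Wilcoxon rank-sum / signed-rank test
#'
#' Unpaired (Mann-Whitney) for independent samples, paired signed-rank for
#' dependent samples.  Exact enumeration is used when the smaller sample has
#' at most 8 observations and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors; equal length when `paired = TRUE`.
#' @param paired Use the paired signed-rank test.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A test-result object with statistic, p-value and sample sizes.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop("empty input vector")
  if (paired && length(x) != length(y)) stop("paired samples must have equal length")
  if (paired) {
    d <- x - y
    if (all(d == 0)) {
      # degenerate: no signal at all
      return(new_test_result(0, 1, "exact", length(x), length(y)))
    }
    ties <- any(duplicated(abs(d[d != 0]))) || any(d == 0)
    exact <- sum(d != 0) <= 8L && !ties
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, paired = TRUE, exact = exact, correct = TRUE,
      alternative = alternative))
  } else {
    ties <- any(duplicated(c(x, y)))
    exact <- min(length(x), length(y)) <= 8L && !ties
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, paired = FALSE, exact = exact, correct = TRUE,
      alternative = alternative))
  }
  new_test_result(wt$statistic, wt$p.value,
                  if (exact) "exact" else "asymptotic",
                  length(x), length(y))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution with effective sample
#' size n1 n2 / (n1 + n2).
#'
#' @param x,y Numeric vectors.
#' @return A test-result object (statistic = D).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("empty input vector")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  new_test_result(kt$statistic, kt$p.value, "asymptotic",
                  length(x), length(y))
}

# Midranks of the pooled sample and tie-averaged Ansari-Bradley scores.
# Ansari scores over sorted positions are a_i = min(i, N + 1 - i); tied
# values receive the mean score of the positions their block occupies.
lepage_scores <- function(z) {
  N <- length(z)
  pos_scores <- pmin(seq_len(N), N + 1 - seq_len(N))
  o <- order(z)
  sc <- numeric(N)
  sc[o] <- stats::ave(pos_scores, factor(z[o]), FUN = mean)
  list(ranks = rank(z, ties.method = "average"), ansari = sc)
}

lepage_statistic <- function(rsum, asum, n1, n2) {
  N <- n1 + n2
  ew <- n1 * (N + 1) / 2
  vw <- n1 * n2 * (N + 1) / 12
  if (N %% 2 == 0) {
    ec <- n1 * (N + 2) / 4
    vc <- n1 * n2 * (N + 2) * (N - 2) / (48 * (N - 1))
  } else {
    ec <- n1 * (N + 1)^2 / (4 * N)
    vc <- n1 * n2 * (N + 1) * (3 + N^2) / (48 * N^2)
  }
  zl <- (rsum - ew)^2 / vw
  zs <- (asum - ec)^2 / vc
  c(location = zl, scale = zs, L = zl + zs)
}

#' Lepage joint location-scale test
#'
#' Combines the Wilcoxon rank-sum statistic W (location) and the
#' Ansari-Bradley score sum C (scale) of the first sample into
#' L = (W - E\[W\])^2/Var\[W\] + (C - E\[C\])^2/Var\[C\], compared to a
#' chi-square distribution with 2 df (asymptotic method) or to its
#' permutation null.  Ties invalidate the no-tie moments, so with tied data
#' the asymptotic method falls back to a permutation p-value (exhaustive
#' when the number of group assignments is at most 20,000, otherwise seeded
#' Monte Carlo with an add-one estimator).
#'
#' @param x,y Numeric vectors with at least two values each.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration is
#'   infeasible (default 10000).
#' @param seed Seed for Monte-Carlo permutation (default 42).
#' @return A test-result object; `components` holds the location and scale
#'   Z^2 terms.
#' @examples
#' lepage_test(c(1, 2, 3), c(4, 5, 6))
#' @export
lepage_test <- function(x, y, method = c("asymptotic", "permutation"),
                        n_perm = 10000, seed = 42) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  z <- c(x, y)
  N <- n1 + n2
  sco <- lepage_scores(z)
  obs <- lepage_statistic(sum(sco$ranks[seq_len(n1)]),
                          sum(sco$ansari[seq_len(n1)]), n1, n2)
  ties <- any(duplicated(z))
  if (method == "asymptotic" && ties) {
    warning("ties present; falling back to permutation null for the Lepage test")
    method <- "permutation"
  }
  if (method == "asymptotic") {
    p <- stats::pchisq(obs[["L"]], df = 2, lower.tail = FALSE)
    return(new_test_result(obs[["L"]], p, "asymptotic", n1, n2,
                           components = obs[c("location", "scale")]))
  }
  eps <- 1e-9
  if (choose(N, n1) <= 20000) {
    idx <- utils::combn(N, n1)
    lstar <- apply(idx, 2L, function(i) {
      lepage_statistic(sum(sco$ranks[i]), sum(sco$ansari[i]), n1, n2)[["L"]]
    })
    p <- mean(lstar >= obs[["L"]] - eps)
  } else {
    lstar <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      i <- sample.int(N, n1)
      lepage_statistic(sum(sco$ranks[i]), sum(sco$ansari[i]), n1, n2)[["L"]]
    }, numeric(1)))
    p <- (1 + sum(lstar >= obs[["L"]] - eps)) / (n_perm + 1)
  }
  new_test_result(obs[["L"]], p, "permutation", n1, n2,
                  components = obs[c("location", "scale")])
}

#' Fisher's exact test on a contingency table
#'
#' 2x2 tables use the exact two-sided probability-mass criterion (sum of
#' hypergeometric probabilities no larger than the observed table's).
#' Larger tables use a seeded Monte-Carlo permutation p-value at fixed
#' margins.
#'
#' @param table Matrix of non-negative integer counts, at least 2x2.
#' @param n_perm Monte-Carlo replicates for tables larger than 2x2.
#' @param seed Seed for the Monte-Carlo path.
#' @return A test-result object (statistic = odds-ratio estimate for 2x2,
#'   NA otherwise; n1/n2 are the table margins' totals).
#' @export
fisher_exact <- function(table, n_perm = 10000, seed = 42) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)) || any(!is.finite(table))) {
    stop("contingency table entries must be non-negative integers")
  }
  if (nrow(table) < 2L || ncol(table) < 2L) stop("table must be at least 2x2")
  if (nrow(table) == 2L && ncol(table) == 2L) {
    ft <- stats::fisher.test(table)
    return(new_test_result(unname(ft$estimate), ft$p.value, "exact",
                           sum(table[1, ]), sum(table[2, ])))
  }
  ft <- with_seed(seed, stats::fisher.test(table, simulate.p.value = TRUE,
                                           B = n_perm))
  new_test_result(NA_real_, ft$p.value, "permutation",
                  sum(table[1, ]), sum(table) - sum(table[1, ]))
}

#' Kruskal-Wallis omnibus test with post-hoc pairwise Wilcoxon
#'
#' Tie-corrected Kruskal-Wallis H with chi-square (g - 1 df) p-value;
#' when the omnibus p-value falls below `posthoc_threshold`, all pairwise
#' unpaired two-sided Wilcoxon tests are run and BH-adjusted across pairs.
#'
#' @param groups List of (non-empty) numeric vectors, one per group.
#' @param posthoc_threshold Omnibus p-value below which the pairwise tests
#'   run (default 0.05).
#' @return List with `omnibus` (test-result) and `pairwise` (symmetric
#'   matrix of BH-adjusted p-values, NA when the omnibus was not
#'   significant).
#' @export
kruskal_posthoc <- function(groups, posthoc_threshold = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 1L)) stop("empty group")
  g <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(g))
  kt <- stats::kruskal.test(groups)
  omni <- new_test_result(kt$statistic, kt$p.value, "asymptotic",
                          length(groups[[1]]), length(unlist(groups[-1])))
  pw <- matrix(NA_real_, g, g, dimnames = list(names(groups), names(groups)))
  if (omni$p_value < posthoc_threshold) {
    pairs <- utils::combn(g, 2)
    praw <- apply(pairs, 2L, function(ij) {
      wilcoxon_test(groups[[ij[1]]], groups[[ij[2]]])$p_value
    })
    padj <- adjust_pvalues(praw, "BH")
    for (k in seq_len(ncol(pairs))) {
      pw[pairs[1, k], pairs[2, k]] <- pw[pairs[2, k], pairs[1, k]] <- padj[k]
    }
  }
  list(omnibus = omni, pairwise = pw)
}

#' Standardized mean difference
#'
#' d = (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2), using n-1 sample
#' variances and pooling without sample-size weighting.  Conventional
#' magnitude bands are small/medium/large at |d| >= 0.2 / 0.5 / 0.8.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @return The standardized mean difference (scalar).
#' @seealso [smd_band()]
#' @export
standardized_mean_difference <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  s <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (s == 0) stop("pooled standard deviation is zero; d undefined")
  (mean(x) - mean(y)) / s
}

#' Effect-size band for a standardized mean difference
#'
#' @param d Standardized mean difference(s).
#' @return Character vector: "negligible", "small", "medium" or "large".
#' @export
smd_band <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

# Run `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
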