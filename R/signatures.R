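#' Gene-set machinery
#'
#' GMT I/O, preranked gene-set enrichment with permutation nulls,
#' single-sample enrichment scores, per-cell rank-cap signature scores and
#' hypergeometric over-representation tests.
#'
#' @name signatures
NULL

#' Read a GMT gene-set file
#'
#' Standard GMT lines: set name, description, then tab-separated gene
#' symbols.  Lines with fewer than three fields are skipped with a
#' warning; duplicate genes within a set are removed.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) warning(sum(short), " GMT lines with < 3 fields skipped")
  parts <- parts[!short]
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors (descriptions taken from
#'   attribute `descriptions` when present).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

# Enrichment score from hit positions in a list sorted by decreasing
# statistic.  Hits step up by |stat|^w / sum, misses step down by
# 1/(N - n_hits); the running sum is piecewise linear, so extrema occur at
# a hit or immediately before one.
es_from_positions <- function(pos, absw_sorted, N) {
  pos <- sort(pos)
  w <- absw_sorted[pos]
  sw <- sum(w)
  nh <- length(pos)
  miss <- 1 / (N - nh)
  if (sw == 0) return(0)
  after <- cumsum(w) / sw - (pos - seq_len(nh)) * miss
  before <- after - w / sw
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Genes are sorted by decreasing statistic; the weighted running sum
#' (hit increment |stat|^`weight_p`, miss decrement 1/(N - n_hits)) gives
#' the signed enrichment score ES.  The null is generated by gene-label
#' permutation; the p-value is the permutation tail for the observed sign
#' (add-one estimator) and NES divides ES by the mean |null ES| of the same
#' sign.  BH adjustment across sets; the leading edge is the set genes up
#' to the running-sum extremum.
#'
#' @param stats_vec Named numeric vector of per-gene ranking statistics
#'   (no missing values).
#' @param sets Named list of gene sets.
#' @param weight_p Statistic weight exponent (default 1).
#' @param n_perm Permutations per set (default 10000).
#' @param seed RNG seed (default 42).
#' @param min_size,max_size Set-size bounds after universe intersection
#'   (defaults 5 and 500).
#' @return Data frame: set, size, ES, NES, p, adj_p, leading_edge
#'   (comma-joined).
#' @export
preranked_gsea <- function(stats_vec, sets, weight_p = 1, n_perm = 10000,
                           seed = 42, min_size = 5, max_size = 500) {
  if (any(is.na(stats_vec))) stop("ranking statistics must not be missing")
  if (length(unique(stats_vec)) == 1L) stop("all statistics equal; no ranking")
  ord <- order(stats_vec, decreasing = TRUE)
  sorted_genes <- names(stats_vec)[ord]
  absw <- abs(stats_vec[ord])^weight_p
  N <- length(stats_vec)
  sets <- lapply(sets, intersect, names(stats_vec))
  sizes <- vapply(sets, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  with_seed(seed, {
    rows <- lapply(names(sets), function(nm) {
      genes <- sets[[nm]]
      pos <- sort(match(genes, sorted_genes))
      es <- es_from_positions(pos, absw, N)
      null_es <- vapply(seq_len(n_perm), function(b) {
        es_from_positions(sample.int(N, length(pos)), absw, N)
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(es)]
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      # leading edge: hits up to (and including) the extremum position
      w <- absw[pos]; sw <- sum(w); nh <- length(pos)
      after <- cumsum(w) / sw - (pos - seq_len(nh)) * (1 / (N - nh))
      before <- after - w / sw
      if (es >= 0) {
        cut_at <- pos[which.max(after)]
        le <- sorted_genes[pos[pos <= cut_at]]
      } else {
        cut_at <- pos[which.min(before)]
        le <- sorted_genes[pos[pos >= cut_at]]
      }
      data.frame(set = nm, size = nh, ES = es, NES = nes, p = p,
                 leading_edge = paste(le, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      return(data.frame(set = character(0), size = integer(0),
                        ES = numeric(0), NES = numeric(0), p = numeric(0),
                        adj_p = numeric(0), leading_edge = character(0)))
    }
    out$adj_p <- adjust_pvalues(out$p, "BH")
    out[, c("set", "size", "ES", "NES", "p", "adj_p", "leading_edge")]
  })
}

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression (1 = lowest); the score is
#' the sum of running-sum deviations of a rank-weighted (rank^`alpha`)
#' hit/miss walk down the ranking.  Optional normalization divides all
#' scores by the global (max - min).
#'
#' @param expr Genes x samples expression matrix.
#' @param sets Named list of gene sets.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide by the global score range (default TRUE).
#' @return Samples x sets score matrix.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  x <- as.matrix(expr)
  sets <- lapply(sets, intersect, rownames(x))
  drop <- vapply(sets, length, 1L) < 2L
  if (any(drop)) {
    message(sum(drop), " sets with < 2 genes in the universe skipped")
  }
  sets <- sets[!drop]
  if (!length(sets)) stop("no usable gene sets")
  G <- nrow(x)
  scores <- matrix(NA_real_, ncol(x), length(sets),
                   dimnames = list(colnames(x), names(sets)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")        # 1 = lowest
    ord <- order(r, decreasing = TRUE)                # walk from the top
    rw <- r[ord]^alpha
    for (k in seq_along(sets)) {
      hit <- rownames(x)[ord] %in% sets[[k]]
      wh <- rw * hit
      p_hit <- cumsum(wh) / sum(wh)
      p_miss <- cumsum(!hit) / (G - sum(hit))
      scores[j, k] <- sum(p_hit - p_miss)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  scores
}

#' Per-cell rank-cap signature scores
#'
#' Mann-Whitney-style signature score per cell: expression ranks
#' (descending, ties averaged) are clamped at `max_rank` + 1 beyond
#' `max_rank`; U' = sum of clamped set ranks - n(n+1)/2 and the score is
#' 1 - U'/(n max_rank), floored at 0, so it lies in \[0, 1\].
#'
#' @param expr Cells x genes expression matrix.
#' @param set Character vector of signature genes.
#' @param max_rank Rank cap (default 1500, limited to the gene count).
#' @return Per-cell numeric scores (NA if no signature gene is measured).
#' @export
cell_signature_scores <- function(expr, set, max_rank = 1500) {
  x <- as.matrix(expr)
  if (max_rank > ncol(x)) max_rank <- ncol(x)
  genes <- intersect(set, colnames(x))
  if (!length(genes)) {
    return(stats::setNames(rep(NA_real_, nrow(x)), rownames(x)))
  }
  n <- length(genes)
  out <- apply(x, 1L, function(v) {
    r <- rank(-v, ties.method = "average")
    r <- pmin(r, max_rank + 1)
    u <- sum(r[match(genes, colnames(x))]) - n * (n + 1) / 2
    max(0, 1 - u / (n * max_rank))
  })
  stats::setNames(out, rownames(x))
}

#' Hypergeometric over-representation test
#'
#' One-sided over-representation p per set for a hit list within a
#' universe; BH adjustment across sets; fold enrichment = observed /
#' expected overlap.
#'
#' @param hits Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of all considered genes.
#' @param sets Named list of gene sets (intersected with the universe).
#' @return Data frame: set, size, overlap, fold_enrichment, p, adj_p.
#' @export
ora_test <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  if (!length(hits)) stop("empty hit list")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  sets <- lapply(sets, intersect, universe)
  Nu <- length(universe); nh <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    k <- length(intersect(hits, sets[[nm]]))
    p <- stats::phyper(k - 1, m, Nu - m, nh, lower.tail = FALSE)
    expct <- nh * m / Nu
    data.frame(set = nm, size = m, overlap = k,
               fold_enrichment = if (expct > 0) k / expct else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_pvalues(out$p, "BH")
  out
}
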