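test_that("median-of-ratios size factors match hand values and the
           reference implementation", {
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(size_factors(cbind(m[, 1], m[, 1])), c(1, 1))
  two <- cbind(a = c(10, 30), b = c(20, 60))
  expect_equal(size_factors(two), c(1 / sqrt(2), sqrt(2)))
  # invariant to gene order
  set.seed(20)
  big <- matrix(rnbinom(600, mu = 50, size = 5) + 1, 100, 6)
  expect_equal(size_factors(big), size_factors(big[sample(100), ]))
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(big)
  expect_equal(size_factors(big), unname(ref), tolerance = 1e-8)
})

test_that("size factors fall back to total counts when zeros pervade", {
  m <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_warning(sf <- size_factors(m), "total-count")
  expect_equal(sf, c(1, 1))
})

test_that("log transform values and scale invariance", {
  m <- matrix(c(0, 7), 1, 2)
  lx <- log_transform(m, factors = c(1, 1))
  expect_equal(as.numeric(lx), c(0, 3))
  m2 <- matrix(rpois(40, 20), 10, 4) + 1
  f <- c(0.5, 1, 1.5, 2)
  expect_equal(unclass(log_transform(m2 * 2, f * 2))[, ],
               unclass(log_transform(m2, f))[, ])
  expect_error(log_transform(m2, c(-1, 1, 1, 1)), "positive")
})

test_that("batch adjustment removes an additive shift and keeps biology", {
  set.seed(21)
  n <- 24
  samples <- data.frame(
    subject = paste0("s", 1:n),
    lineage = rep(c("LEP", "MEP"), n / 2),
    age = rep(c("young", "old"), each = n / 2),
    batch = rep(rep(c("b1", "b2"), each = 2), times = n / 4))
  beta <- 2
  x <- matrix(rnorm(50 * n, 5), 50, n,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:n)))
  x[, samples$lineage == "MEP"] <- x[, samples$lineage == "MEP"] + beta
  x_b <- x; x_b[, samples$batch == "b2"] <- x_b[, samples$batch == "b2"] + 1
  adj <- adjust_batch(x_b, samples)
  bdiff <- rowMeans(adj[, samples$batch == "b2"]) -
    rowMeans(adj[, samples$batch == "b1"])
  expect_lt(max(abs(bdiff)), 0.05)
  gdiff <- rowMeans(adj[, samples$lineage == "MEP"]) -
    rowMeans(adj[, samples$lineage == "LEP"])
  expect_equal(mean(gdiff), beta, tolerance = 0.2)
  # balanced batches leave the overall gene mean unchanged
  expect_equal(rowMeans(adj), rowMeans(x_b), tolerance = 1e-8)
  # single batch: identity
  samples1 <- samples; samples1$batch <- "b1"
  expect_equal(unclass(adjust_batch(x, samples1))[, ], x[, ])
})

test_that("batch confounded with the design is refused", {
  samples <- data.frame(subject = paste0("s", 1:8),
                        lineage = rep(c("LEP", "MEP"), each = 4),
                        age = "young",
                        batch = rep(c("b1", "b2"), each = 4))
  x <- matrix(rnorm(80), 10, 8)
  expect_error(adjust_batch(x, samples), "confounded")
})

test_that("subject aggregation averages replicates and is idempotent", {
  samples <- data.frame(subject = c("u1", "u1", "u2"),
                        lineage = "LEP", age = "young", batch = "b1")
  x <- matrix(c(1, 3, 7), 1, 3,
              dimnames = list("g1", c("a", "b", "c")))
  agg <- aggregate_subjects(x, samples)
  expect_equal(as.numeric(agg$expr), c(2, 7))
  agg2 <- aggregate_subjects(agg$expr, agg$samples)
  expect_equal(unclass(agg2$expr)[, ], unclass(agg$expr)[, ])
})

test_that("expression filter applies the cell-wise rule", {
  samples <- data.frame(lineage = rep(c("LEP", "MEP"), each = 4),
                        age = "young")
  counts <- rbind(zero = rep(0, 8),
                  lep_only = c(20, 20, 20, 20, 0, 0, 0, 0),
                  weak = c(2, 0, 0, 1, 1, 0, 2, 0))
  kept <- filter_expressed(counts, samples, min_count = 10,
                           min_fraction = 0.7)
  expect_identical(kept, "lep_only")
  expect_identical(filter_expressed(counts, samples, min_count = 0,
                                    min_fraction = 0.5),
                   rownames(counts))
})

test_that("concordance filter reports R2 and drops sign-flipped genes", {
  set.seed(22)
  g <- paste0("g", 1:100)
  a <- matrix(rnorm(100 * 4, 6), 100, 4, dimnames = list(g, NULL))
  deA <- fake_de(g, lfc = rep(0, 100), adj_p = 1)
  deA$lfc[1] <- 2
  deB <- fake_de(g, lfc = rep(0, 100), adj_p = 1)
  deB$lfc[1] <- -2
  same <- suppressWarnings(concordance_filter(a, a, deA, deA))
  expect_equal(same$r2, 1)
  expect_equal(length(same$retained), 100)
  flip <- concordance_filter(a, a + rnorm(400, 0, 0.1), deA, deB)
  expect_false("g1" %in% flip$retained)
  # independent noise lowers R2 monotonically on average
  r2s <- sapply(c(0.1, 0.5, 2), function(s) {
    concordance_filter(a, a + matrix(rnorm(400, 0, s), 100, 4),
                       deA, deA)$r2
  })
  expect_true(all(diff(r2s) < 0))
  expect_error(concordance_filter(a[1:5, ], a[1:5, ], deA, deA), "10")
})

test_that("quantile shift matrices are conservative counts", {
  set.seed(23)
  y <- matrix(rnorm(200 * 8, 5), 200, 8,
              dimnames = list(paste0("g", 1:200), NULL))
  qs <- quantile_shift(y, y)
  expect_true(all(qs$mean_transition[row(qs$mean_transition) !=
                                     col(qs$mean_transition)] == 0))
  expect_equal(sum(qs$mean_transition), 200)
  expect_equal(sum(qs$variance_transition), 200)
  # uniform x4 variance inflation pushes variance bins upward
  o <- 5 + (y - 5) * 2
  qs2 <- quantile_shift(y, o)
  up <- sum(qs2$variance_transition[upper.tri(qs2$variance_transition)])
  dn <- sum(qs2$variance_transition[lower.tri(qs2$variance_transition)])
  expect_gt(up, dn)
  expect_true(all(qs2$variance_transition >= 0))
})

test_that("sample clustering separates lineages and ignores gene order", {
  x <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 2))
  rownames(x) <- paste0("g", 1:3)
  hc <- cluster_samples(x)
  expect_equal(hc$height[1], 0)
  set.seed(24)
  sim <- simulate_dataset(default_config())
  lx <- log_transform(sim$counts)
  spec_genes <- sim$truth$gene[sim$truth$class != "null"]
  hc2 <- cluster_samples(lx, spec_genes)
  cl <- cutree(hc2, 2)
  truth_cl <- as.integer(factor(sim$samples$lineage))
  tab <- table(cl, truth_cl)
  agree <- (sum(choose(tab, 2)) +
            choose(sum(tab), 2) - sum(choose(rowSums(tab), 2)) -
            sum(choose(colSums(tab), 2)) + sum(choose(tab, 2))) /
    choose(sum(tab), 2)
  rand_index <- agree
  expect_gte(rand_index, 0.95)
  # gene order invariance
  hc3 <- cluster_samples(lx[sample(nrow(lx)), ], spec_genes)
  expect_equal(cutree(hc3, 2)[names(cl)], cl)
  expect_error(cluster_samples(x[, 1, drop = FALSE]), "2 samples")
})
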