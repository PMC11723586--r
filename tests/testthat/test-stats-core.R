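test_that("BH and Bonferroni adjustments follow the step-up/cap rules", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(adjust_pvalues(c(0.5, 0.5), "bonferroni"), c(1, 1))
  expect_equal(adjust_pvalues(0.037), 0.037)
  # missing values propagate and are excluded from m
  expect_equal(adjust_pvalues(c(0.01, NA, 0.02)),
               c(0.02, NA, 0.02))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")

  set.seed(1)
  p <- runif(50)
  bh <- adjust_pvalues(p)
  bf <- adjust_pvalues(p, "bonferroni")
  expect_true(all(bh >= p))
  expect_true(all(bf >= bh - 1e-12))
  # monotone in rank order
  o <- order(p)
  expect_true(all(diff(bh[o]) >= -1e-12))
})

test_that("wilcoxon test switches between exact and approximate correctly", {
  r <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)   # 2/20 orderings as extreme, both tails
  expect_identical(r$method, "exact")
  # paired with all-zero differences is a defined degenerate case
  r0 <- wilcoxon_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r0$p_value, 1)
  # identical large samples: p near 1
  set.seed(2)
  x <- rnorm(60)
  rl <- wilcoxon_test(x, sample(x))
  expect_identical(rl$method, "asymptotic")
  expect_gt(rl$p_value, 0.8)
  expect_error(wilcoxon_test(numeric(0), 1:3), "empty")
})

test_that("KS two-sample statistic and invariances", {
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)
  same <- ks_two_sample(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # D invariant under strictly monotone transforms of both samples
  set.seed(3)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  d0 <- ks_two_sample(x, y)$statistic
  expect_equal(ks_two_sample(exp(x), exp(y))$statistic, d0)
  expect_equal(ks_two_sample(atan(x), atan(y))$statistic, d0)
})

test_that("Lepage worked example and component decomposition", {
  r <- lepage_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, (6 - 10.5)^2 / 5.25, tolerance = 1e-10)
  expect_equal(unname(r$components[["scale"]]), 0)
  expect_equal(r$p_value, exp(-r$statistic / 2), tolerance = 1e-10)
  # exhaustive permutation on the same data agrees with hand enumeration
  rp <- lepage_test(c(1, 2, 3), c(4, 5, 6), method = "permutation")
  expect_gte(rp$p_value, 1 / choose(6, 3))
  expect_identical(rp$method, "permutation")
  expect_error(lepage_test(1, c(2, 3)), "at least 2")
})

test_that("Lepage detects a scale-only alternative through the Ansari term", {
  r <- lepage_test(c(-10, -9, 9, 10), c(-2, -1, 1, 2),
                   method = "permutation")
  expect_gt(r$components[["scale"]], r$components[["location"]])
})

test_that("Lepage falls back to permutation under ties", {
  expect_warning(r <- lepage_test(c(1, 1, 2, 3), c(2, 3, 4, 4)),
                 "ties")
  expect_identical(r$method, "permutation")
})

test_that("Lepage asymptotic p tracks the exhaustive permutation null", {
  # the lattice null at n=6/6 is shared by all no-tie data; the continuous
  # chi-square approximation deviates most at mid-range p and is accurate
  # in the decision-relevant tail
  set.seed(4)
  gaps <- t(replicate(200, {
    x <- rnorm(6); y <- rnorm(6)
    pa <- lepage_test(x, y, method = "asymptotic")$p_value
    pp <- lepage_test(x, y, method = "permutation")$p_value
    c(pa = pa, pp = pp)
  }))
  expect_lt(max(abs(gaps[, "pa"] - gaps[, "pp"])), 0.07)
  tail_sel <- gaps[, "pp"] < 0.1
  expect_gt(sum(tail_sel), 3)
  expect_lt(max(abs(gaps[tail_sel, "pa"] - gaps[tail_sel, "pp"])), 0.03)
})

test_that("Lepage permutation p is calibrated under the null", {
  set.seed(5)
  rej <- mean(replicate(2000, {
    lepage_test(rnorm(6), rnorm(6), method = "permutation")$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Fisher exact test matches enumeration and symmetries", {
  r <- fisher_exact(matrix(c(2, 0, 0, 2), 2))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-10)
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1)
  m <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_exact(m)$p_value, fisher_exact(t(m))$p_value)
  expect_equal(fisher_exact(m)$p_value, fisher_exact(m[2:1, ])$p_value)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(0.5, 2, 3, 4), 2)), "non-negative")
  # r x c Monte-Carlo path is seeded and reproducible
  m3 <- matrix(c(8, 1, 1, 1, 7, 2, 2, 1, 9), 3)
  expect_equal(fisher_exact(m3, n_perm = 2000, seed = 7)$p_value,
               fisher_exact(m3, n_perm = 2000, seed = 7)$p_value)
})

test_that("Kruskal-Wallis omnibus and post-hoc behave per contract", {
  r <- kruskal_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(unname(r$omnibus$statistic), 7.2, tolerance = 1e-10)
  expect_true(all(!is.na(r$pairwise[upper.tri(r$pairwise)])))
  # identical groups: omnibus non-significant, no pairwise tests run
  same <- kruskal_posthoc(list(1:5, 1:5, 1:5))
  expect_gt(same$omnibus$p_value, 0.9)
  expect_true(all(is.na(same$pairwise)))
  # two groups: H = Z^2 correspondence with the normal-approx Wilcoxon
  set.seed(6)
  x <- rnorm(30); y <- rnorm(30, 1)
  kw <- kruskal_posthoc(list(x, y))$omnibus
  wz <- qnorm(wilcoxon_test(x, y)$p_value / 2)
  expect_equal(unname(kw$statistic), wz^2, tolerance = 0.05)
  expect_error(kruskal_posthoc(list(1:3)), "2 groups")
})

test_that("standardized mean difference arithmetic and antisymmetry", {
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(0, 1, 2)), 1)
  expect_equal(standardized_mean_difference(1:4, 1:4), 0)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(standardized_mean_difference(x, y),
               -standardized_mean_difference(y, x))
  expect_error(standardized_mean_difference(c(1, 1), c(1, 1)), "zero")
  expect_equal(as.character(smd_band(c(0.1, 0.3, 0.6, 1.2))),
               c("negligible", "small", "medium", "large"))
})
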