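test_that("specificity calls follow the threshold rules", {
  de <- fake_de(paste0("g", 1:4),
                lfc = c(-2, 0.5, 3, 3),
                adj_p = c(1e-5, 1e-5, 0.01, 1e-4))
  call <- classify_specificity(de)
  expect_equal(unname(call), c("LEP", "none", "none", "MEP"))
  age <- fake_de("g1", 1, 0.01, contrast = "OldvsYoung_LEP")
  expect_error(classify_specificity(age), "MEP-vs-LEP")
})

test_that("strata transitions partition the gene universe", {
  genes <- paste0("g", 1:4)
  dy <- fake_de(genes, lfc = c(-2, 2, -2, 0), adj_p = c(1e-5, 1e-5, 1e-5, 1))
  do <- fake_de(genes, lfc = c(-2, 2, 0, 2), adj_p = c(1e-5, 1e-5, 1, 1e-5),
                contrast = "MEPvsLEP_old")
  st <- build_strata(dy, do)
  expect_equal(unname(st$counts["maintained"]), 2L)
  expect_equal(unname(st$counts["lost"]), 1L)
  expect_equal(unname(st$counts["gained"]), 1L)
  # identical cohorts: everything specific is maintained
  st0 <- build_strata(dy, dy)
  expect_equal(unname(st0$counts["lost"]), 0L)
  expect_equal(unname(st0$counts["maintained"]),
               unname(st0$counts["young_specific"]))
  # partition identities
  expect_equal(unname(st$counts["maintained"] + st$counts["lost"]),
               unname(st$counts["young_specific"]))
  expect_equal(sum(st$counts[c("maintained", "lost", "gained", "none")]),
               nrow(st$table))
})

test_that("strata recovery tracks engineered loss within tolerance", {
  cfg <- default_config()
  cfg$frac_fidelity_loss_via_de <- 0.3
  cfg$frac_fidelity_loss_via_dv <- 0.3
  cfg$seed <- 50L
  sim <- simulate_dataset(cfg)
  dy <- run_de(sim$counts, sim$samples, "MEPvsLEP_young")
  do <- run_de(sim$counts, sim$samples, "MEPvsLEP_old")
  st <- build_strata(dy, do)
  lost <- st$table$transition %in% c("lost", "switched")
  # most via_DE genes are detected as lost
  via_de <- sim$truth$mechanism == "via_DE"
  called_spec <- st$table$specificity_young != "none"
  expect_gte(mean(lost[via_de & called_spec]), 0.7)
})

test_that("fold-change shift statistics behave on constructions", {
  genes <- paste0("g", 1:100)
  set.seed(51)
  lfc <- c(-(1:50) / 10 - 1, (1:50) / 10 + 1)
  dy <- fake_de(genes, lfc, adj_p = 1e-5)
  # identical cohorts: no shift signal
  same <- lfc_shift_report(dy, dy, genes)
  expect_equal(same$ks$statistic, 0)
  expect_equal(same$frac_larger_young, 0)
  expect_gte(same$t_p, 0.99)
  # halved old-cohort magnitudes: total shift
  do <- fake_de(genes, lfc * 0.5, adj_p = 1e-5, contrast = "MEPvsLEP_old")
  shift <- lfc_shift_report(dy, do, genes)
  expect_equal(shift$frac_larger_young, 1)
  expect_lt(shift$t_p, 1e-6)
  expect_lt(shift$ks$p_value, 0.01)
  # attenuation toward zero counts as larger-in-young for negative lfc too
  lep_only <- genes[lfc < 0]
  shift_lep <- lfc_shift_report(dy, do, lep_only)
  expect_equal(shift_lep$frac_larger_young, 1)
  expect_error(lfc_shift_report(dy, do, character(0)), "empty")
})

test_that("attribution arithmetic matches the worked example", {
  genes <- paste0("g", 1:12)
  dy <- fake_de(genes, lfc = rep(-2, 12), adj_p = 1e-5)
  do <- fake_de(genes, lfc = c(rep(-2, 2), rep(0, 10)),
                adj_p = c(rep(1e-5, 2), rep(1, 10)),
                contrast = "MEPvsLEP_old")
  st <- build_strata(dy, do)   # 10 lost genes: g3..g12
  age_lfc <- rep(0, 12); age_lfc[3:5] <- 1.5       # 3 with |age lfc| >= 1
  age_p <- rep(1, 12)
  de_lep <- fake_de(genes, age_lfc, adj_p = age_p,
                    contrast = "OldvsYoung_LEP")
  de_mep <- fake_de(genes, rep(0, 12), adj_p = 1,
                    contrast = "OldvsYoung_MEP")
  fold <- rep(1, 12); fold[4:7] <- 2.5             # 4 with var fold >= 2
  vr <- data.frame(gene = genes, var_young = 1, var_old = fold,
                   fold = fold)
  vr0 <- data.frame(gene = genes, var_young = 1, var_old = 1, fold = 1)
  att <- attribute_loss(st, de_lep, de_mep, vr, vr0)
  expect_equal(att$n_lost, 10L)
  expect_equal(att$via_2fold_DE, 0.3)
  expect_equal(att$via_2fold_DV, 0.4)
  expect_equal(att$overlap, 0.2)
  expect_equal(att$unexplained, 0.5)
  # identity: via_DE + via_DV - overlap + unexplained = 1
  expect_equal(att$via_2fold_DE + att$via_2fold_DV - att$overlap +
                 att$unexplained, 1)
  # duplication invariance
  att2 <- attribute_loss(st, rbind(de_lep, de_lep), de_mep, vr, vr0)
  expect_equal(att2$via_2fold_DE, att$via_2fold_DE)
  # empty lost set reports NA
  st_none <- build_strata(dy, dy)
  expect_true(is.na(attribute_loss(st_none, de_lep, de_mep, vr,
                                   vr0)$via_2fold_DE))
})

test_that("attribution stays near the false-positive floor without age
           effects", {
  cfg <- default_config()
  cfg$frac_fidelity_loss_via_de <- 0
  cfg$frac_fidelity_loss_via_dv <- 0
  cfg$frac_age_de_lep <- cfg$frac_age_de_mep <- 0
  cfg$frac_age_dv_lep <- cfg$frac_age_dv_mep <- 0
  cfg$seed <- 52L
  sim <- simulate_dataset(cfg)
  dy <- run_de(sim$counts, sim$samples, "MEPvsLEP_young")
  do <- run_de(sim$counts, sim$samples, "MEPvsLEP_old")
  dal <- run_de(sim$counts, sim$samples, "OldvsYoung_LEP")
  dam <- run_de(sim$counts, sim$samples, "OldvsYoung_MEP")
  st <- build_strata(dy, do)
  agg <- aggregate_subjects(adjust_batch(log_transform(sim$counts),
                                         sim$samples), sim$samples)
  att <- attribute_loss(st, dal, dam,
                        variance_ratio(agg$expr, agg$samples, "LEP"),
                        variance_ratio(agg$expr, agg$samples, "MEP"))
  expect_lt(att$via_sig_DE, 0.15)
  expect_lt(att$via_2fold_DE, 0.15)
})

test_that("direction summary identifies movement toward the opposite
           lineage", {
  genes <- paste0("g", 1:10)
  # LEP-specific genes (negative lineage lfc) rising in old LEPs move
  # toward the MEP level ... here sign(age lfc) = sign(lineage lfc)
  dl <- fake_de(genes, lfc = rep(-2, 10), adj_p = 1e-5)
  age <- fake_de(genes, lfc = rep(-1, 10), adj_p = 0.01,
                 contrast = "OldvsYoung_LEP")
  ds <- direction_summary(age, dl, "LEP")
  expect_equal(ds$frac_toward_opposite, 1)
  expect_equal(ds$n_down, 10L)
  # no significant genes
  age_ns <- fake_de(genes, lfc = rep(-1, 10), adj_p = 0.5,
                    contrast = "OldvsYoung_LEP")
  ds0 <- direction_summary(age_ns, dl, "LEP")
  expect_equal(ds0$n_up + ds0$n_down, 0L)
  expect_true(is.na(ds0$frac_toward_opposite))
  # for MEP the opposite sign counts as toward-LEP
  dsm <- direction_summary(age, dl, "MEP")
  expect_equal(dsm$frac_toward_opposite, 0)
})
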