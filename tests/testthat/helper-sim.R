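# Shared fixture builders for the test suite.

# A configuration with every engineered effect switched off.
null_sim_config <- function(n_genes = 500, n_young = 8, n_old = 8,
                            seed = 42) {
  cfg <- default_config()
  cfg$n_genes <- as.integer(n_genes)
  cfg$n_subjects_young <- as.integer(n_young)
  cfg$n_subjects_old <- as.integer(n_old)
  cfg$replicate_fraction <- 0
  cfg$frac_lep_specific <- cfg$frac_mep_specific <- 0
  cfg$frac_age_de_lep <- cfg$frac_age_de_mep <- 0
  cfg$frac_age_dv_lep <- cfg$frac_age_dv_mep <- 0
  cfg$frac_fidelity_loss_via_de <- cfg$frac_fidelity_loss_via_dv <- 0
  cfg$seed <- as.integer(seed)
  cfg
}

# Minimal DE-result data frame for unit tests that bypass model fitting.
fake_de <- function(genes, lfc, adj_p, p = adj_p, contrast = "MEPvsLEP_young") {
  out <- data.frame(gene = genes, lfc = lfc, avg_expr = 5,
                    t = lfc * 10, p = p, adj_p = adj_p,
                    row.names = genes, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  out
}

# 5-class feature matrix with 20 informative features per class.
make_five_class <- function(n_per = 60, n_noise = 100, shift = 1.2,
                            informative = TRUE, seed = 9) {
  set.seed(seed)
  classes <- paste0("C", 1:5)
  y <- factor(rep(classes, each = n_per))
  G <- 5 * 20 + n_noise
  X <- matrix(stats::rnorm(length(y) * G), length(y), G,
              dimnames = list(paste0("s", seq_along(y)), paste0("f", 1:G)))
  if (informative) {
    for (k in 1:5) {
      rows <- y == classes[k]
      cols <- ((k - 1) * 20 + 1):(k * 20)
      X[rows, cols] <- X[rows, cols] + shift
    }
  }
  list(X = X, y = y, informative = paste0("f", 1:100))
}
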