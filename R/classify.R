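#' Multiclass elastic-net tissue classifier
#'
#' SMOTE minority oversampling, repeated stratified cross-validation of an
#' elastic-net multinomial model selected on mean balanced accuracy,
#' multiclass AUC evaluation and scaled variable importance.
#'
#' @name classify
NULL

#' Machine-learning configuration
#'
#' @param cv_folds Cross-validation folds (default 10).
#' @param cv_repeats CV repeats (default 3).
#' @param train_fraction Training split fraction (default 0.75).
#' @param alpha_grid Elastic-net mixing-parameter grid.
#' @param lambda_grid Penalty grid (NULL derives one from the data).
#' @param oversample_k SMOTE neighbours (default 5).
#' @param downsample_majority Also down-sample majority classes to the mean
#'   class size before oversampling (default FALSE).
#' @param seed RNG seed (default 42).
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(cv_folds = 10, cv_repeats = 3, train_fraction = 0.75,
                      alpha_grid = c(0.1, 0.5, 0.9),
                      lambda_grid = NULL, oversample_k = 5,
                      downsample_majority = FALSE, seed = 42) {
  stopifnot(cv_folds >= 2, train_fraction > 0, train_fraction < 1,
            length(alpha_grid) >= 1)
  structure(list(cv_folds = cv_folds, cv_repeats = cv_repeats,
                 train_fraction = train_fraction, alpha_grid = alpha_grid,
                 lambda_grid = lambda_grid, oversample_k = oversample_k,
                 downsample_majority = downsample_majority, seed = seed),
            class = "ml_config")
}

#' SMOTE minority oversampling
#'
#' Upsamples every minority class to the majority-class size with synthetic
#' points x_new = x_i + u (x_nn - x_i), u ~ U(0, 1), where x_nn is one of
#' the `k` nearest same-class neighbours (Euclidean).  A class with a
#' single sample is duplicated with small jitter, with a warning.
#'
#' @param X Samples x features numeric matrix.
#' @param y Class labels (factor or character).
#' @param k Number of nearest neighbours (default 5).
#' @param seed RNG seed (default 42).
#' @return List with balanced `X` and `y`.
#' @export
smote_oversample <- function(X, y, k = 5, seed = 42) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), k >= 1)
  counts <- table(y)
  target <- max(counts)
  if (all(counts == target)) return(list(X = X, y = y))
  with_seed(seed, {
    add_X <- list(); add_y <- list()
    for (cl in names(counts)[counts < target]) {
      idx <- which(y == cl)
      need <- target - length(idx)
      if (length(idx) == 1L) {
        warning("class '", cl, "' has one sample; duplicating with jitter")
        base <- X[rep(idx, need), , drop = FALSE]
        syn <- base + matrix(stats::rnorm(length(base), 0, 1e-6),
                             nrow(base), ncol(base))
      } else {
        Xc <- X[idx, , drop = FALSE]
        d <- as.matrix(stats::dist(Xc))
        diag(d) <- Inf
        kk <- min(k, length(idx) - 1L)
        nn <- matrix(0L, length(idx), kk)
        for (i in seq_along(idx)) nn[i, ] <- order(d[i, ])[seq_len(kk)]
        base_i <- sample.int(length(idx), need, replace = TRUE)
        nb_i <- nn[cbind(base_i, sample.int(kk, need, replace = TRUE))]
        u <- stats::runif(need)
        syn <- Xc[base_i, , drop = FALSE] +
          u * (Xc[nb_i, , drop = FALSE] - Xc[base_i, , drop = FALSE])
      }
      rownames(syn) <- sprintf("syn_%s_%d", cl, seq_len(nrow(syn)))
      add_X[[cl]] <- syn
      add_y[[cl]] <- rep(cl, nrow(syn))
    }
    list(X = rbind(X, do.call(rbind, add_X)),
         y = factor(c(as.character(y), unlist(add_y)), levels = levels(y)))
  })
}

# Stratified fold assignment: within each class, shuffled samples are
# dealt round-robin so every fold sees every class whenever possible.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample.int(n_folds), length(idx))
  }
  fold
}

balanced_accuracy <- function(truth, pred) {
  lev <- levels(truth)
  per_class <- vapply(lev, function(cl) {
    sens <- mean(pred[truth == cl] == cl)
    spec <- mean(pred[truth != cl] != cl)
    (sens + spec) / 2
  }, numeric(1))
  mean(per_class, na.rm = TRUE)
}

#' Train a multiclass elastic-net classifier
#'
#' Repeated stratified k-fold cross-validation over an (alpha, lambda)
#' grid of elastic-net-penalized multinomial logistic models; SMOTE
#' oversampling (and optional majority down-sampling) is applied inside
#' each training fold only, never to validation folds.  The grid point
#' maximizing mean balanced accuracy across folds and repeats is refit on
#' the full (rebalanced) training data.  Features are z-scored internally
#' and the scaling stored for prediction.
#'
#' @param X Samples x features numeric matrix.
#' @param y Class labels.
#' @param config An [ml_config()].
#' @return `fid_fit` list: `coefficients` (classes x features, z-scored
#'   scale), `intercepts`, `alpha`, `lambda`, `cv_table`, `center`,
#'   `scale`, `classes`, `fold_audit`.
#' @export
train_multiclass_enet <- function(X, y, config = ml_config()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, ctr, scl)

  rebalance <- function(Zt, yt, seed) {
    if (config$downsample_majority) {
      target <- ceiling(mean(table(yt)))
      keep <- unlist(lapply(levels(yt), function(cl) {
        idx <- which(yt == cl)
        if (length(idx) > target) sample(idx, target) else idx
      }))
      Zt <- Zt[keep, , drop = FALSE]; yt <- droplevels(yt[keep])
    }
    sm <- smote_oversample(Zt, yt, k = config$oversample_k, seed = seed)
    sm
  }

  with_seed(config$seed, {
    lambda_grid <- config$lambda_grid
    if (is.null(lambda_grid)) {
      pre <- glmnet::glmnet(Z, y, family = "multinomial", alpha = 0.5,
                            nlambda = 30, standardize = FALSE)
      lambda_grid <- pre$lambda[round(seq(1, length(pre$lambda),
                                          length.out = min(5, length(pre$lambda))))]
    }
    grid <- expand.grid(alpha = config$alpha_grid, lambda = lambda_grid)
    acc <- matrix(0, nrow(grid), 0)
    fold_audit <- list()
    for (rep_i in seq_len(config$cv_repeats)) {
      fold <- stratified_folds(y, config$cv_folds)
      for (f in seq_len(config$cv_folds)) {
        tr <- fold != f
        if (length(unique(y[!tr])) < 1L || length(unique(y[tr])) < nlevels(y)) next
        bal <- rebalance(Z[tr, , drop = FALSE], y[tr],
                         seed = config$seed + 1000L * rep_i + f)
        fold_audit[[length(fold_audit) + 1L]] <- list(
          repeat_i = rep_i, fold = f,
          validation_ids = rownames(Z)[!tr],
          synthetic_in_validation = any(grepl("^syn_", rownames(Z)[!tr])))
        fold_acc <- numeric(nrow(grid))
        for (a in unique(grid$alpha)) {
          js <- which(grid$alpha == a)
          fitg <- glmnet::glmnet(bal$X, bal$y, family = "multinomial",
                                 alpha = a, lambda = sort(lambda_grid, TRUE),
                                 standardize = FALSE)
          pr <- predict(fitg, Z[!tr, , drop = FALSE], type = "class",
                        s = grid$lambda[js])
          for (m in seq_along(js)) {
            pred <- factor(pr[, m], levels = levels(y))
            fold_acc[js[m]] <- balanced_accuracy(factor(y[!tr], levels(y)),
                                                 pred)
          }
        }
        acc <- cbind(acc, fold_acc)
      }
    }
    grid$mean_balanced_accuracy <- rowMeans(acc)
    best <- which.max(grid$mean_balanced_accuracy)
    bal <- rebalance(Z, y, seed = config$seed)
    fit <- glmnet::glmnet(bal$X, bal$y, family = "multinomial",
                          alpha = grid$alpha[best],
                          lambda = sort(lambda_grid, TRUE),
                          standardize = FALSE)
    cf <- stats::coef(fit, s = grid$lambda[best])
    B <- t(vapply(cf, function(m) as.numeric(m)[-1], numeric(ncol(Z))))
    dimnames(B) <- list(names(cf), colnames(Z))
    structure(list(
      coefficients = B,
      intercepts = vapply(cf, function(m) as.numeric(m)[1], numeric(1)),
      alpha = grid$alpha[best], lambda = grid$lambda[best],
      cv_table = grid, center = ctr, scale = scl,
      classes = levels(y), fold_audit = fold_audit
    ), class = "fid_fit")
  })
}

# Softmax class probabilities from the stored coefficients.
predict_probs <- function(fit, X) {
  Z <- scale(as.matrix(X), fit$center, fit$scale)
  scores <- Z %*% t(fit$coefficients) +
    matrix(fit$intercepts, nrow(Z), length(fit$classes), byrow = TRUE)
  e <- exp(scores - apply(scores, 1L, max))
  p <- e / rowSums(e)
  colnames(p) <- fit$classes
  p
}

# Rank-statistic (Mann-Whitney) AUC of scores for a binary indicator.
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a multiclass classifier
#'
#' Class probabilities by softmax of the stored linear scores; per-class
#' one-vs-rest AUC by the rank statistic; micro AUC on stacked
#' (sample, class) indicator/probability pairs; macro AUC as the
#' unweighted per-class mean; per-class balanced accuracy and its
#' unweighted mean; confusion matrix of argmax labels.
#'
#' @param fit A `fid_fit` from [train_multiclass_enet()].
#' @param X Samples x features matrix (same features as training).
#' @param y True class labels.
#' @return List: `probabilities`, `labels`, `per_class` (sensitivity,
#'   specificity, balanced_accuracy, auc), `mean_balanced_accuracy`,
#'   `macro_auc`, `micro_auc`, `confusion`.
#' @export
evaluate_multiclass <- function(fit, X, y) {
  y <- factor(y, levels = fit$classes)
  if (any(is.na(y))) stop("labels contain classes unseen during training")
  p <- predict_probs(fit, X)
  labels <- factor(fit$classes[max.col(p, ties.method = "first")],
                   levels = fit$classes)
  per_class <- t(vapply(fit$classes, function(cl) {
    pos <- y == cl
    sens <- mean(labels[pos] == cl)
    spec <- mean(labels[!pos] != cl)
    c(sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2,
      auc = auc_rank(p[, cl], pos))
  }, numeric(4)))
  micro <- auc_rank(as.vector(p),
                    as.vector(outer(y, fit$classes, `==`)))
  list(probabilities = p, labels = labels,
       per_class = as.data.frame(per_class),
       mean_balanced_accuracy = mean(per_class[, "balanced_accuracy"],
                                     na.rm = TRUE),
       macro_auc = mean(per_class[, "auc"], na.rm = TRUE),
       micro_auc = micro,
       confusion = table(truth = y, predicted = labels))
}

#' Scaled variable importance of an elastic-net fit
#'
#' Per class, importance is the absolute coefficient on the z-scored
#' feature scale rescaled so the class maximum equals 100; selected
#' features reach at least `threshold_pct` in at least one class.
#'
#' @param fit A `fid_fit`.
#' @param threshold_pct Selection threshold in percent (default 25).
#' @return List: `importance` (classes x features, 0-100) and `selected`
#'   (character vector of features).
#' @export
variable_importance <- function(fit, threshold_pct = 25) {
  imp <- abs(fit$coefficients)
  mx <- apply(imp, 1L, max)
  zero <- mx == 0
  if (any(zero)) {
    warning("all-zero coefficients for class(es): ",
            paste(rownames(imp)[zero], collapse = ", "))
    mx[zero] <- 1
  }
  imp <- imp / mx * 100
  selected <- colnames(imp)[apply(imp >= threshold_pct, 2L, any)]
  list(importance = imp, selected = selected)
}

#' Stratified train/test split
#'
#' @param y Class labels.
#' @param train_fraction Fraction per class assigned to training
#'   (default 0.75).
#' @param seed RNG seed.
#' @return Logical vector, TRUE for training rows.
#' @export
stratified_split <- function(y, train_fraction = 0.75, seed = 42) {
  y <- as.factor(y)
  with_seed(seed, {
    tr <- logical(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_tr <- max(1L, round(train_fraction * length(idx)))
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
}
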