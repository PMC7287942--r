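test_that("log grid is geometric with inclusive endpoints", {
  g <- log_grid()
  expect_length(g, 7)
  expect_equal(g[1], 0.1)
  expect_equal(g[7], 1000)
  expect_equal(g[4], 10)                      # geometric midpoint
  expect_equal(diff(log(g)), rep(log(10^(2 / 3)), 6))  # 4 decades / 6 steps
  expect_equal(log_grid(k = 2), c(0.1, 1000))
  expect_error(log_grid(lo = -1), "lo")
})

test_that("median/MAD normalization uses raw MAD and train statistics only", {
  nz <- robust_normalize(matrix(c(1, 2, 3), ncol = 1),
                         matrix(4, ncol = 1))
  expect_equal(as.numeric(nz$train), c(-1, 0, 1))
  expect_equal(as.numeric(nz$newdata), 2)     # (4 - 2) / 1, train stats
  expect_equal(unname(nz$scale), 1)           # no 1.4826 consistency factor

  cz <- robust_normalize(matrix(c(5, 5, 5), ncol = 1))
  expect_equal(as.numeric(cz$train), c(0, 0, 0))
  expect_true(cz$mad_zero)

  # mutating the held-out row cannot change the training statistics
  set.seed(3)
  tr <- matrix(rnorm(30), 10, 3)
  a <- robust_normalize(tr, matrix(rnorm(3), 1))
  b <- robust_normalize(tr, matrix(rnorm(3) + 100, 1))
  expect_identical(a$center, b$center)
  expect_identical(a$scale, b$scale)
})

test_that("PCA reduction matches a brute-force eigendecomposition oracle", {
  set.seed(19)
  for (i in 1:5) {
    X <- matrix(rnorm(120), 20, 6)
    p <- pca_reduce(X, 0.95)
    ev <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-8)
    k <- which(cumsum(ev$values) / sum(ev$values) >= 0.95)[1]
    expect_equal(p$n_components, k)
    Xc <- sweep(X, 2, colMeans(X))
    for (j in seq_len(k)) {
      v <- ev$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v     # same sign convention
      expect_equal(p$loadings[, j], v, tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(p$scores[, j], drop(Xc %*% v), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("PCA handles rank-1 and full-variance cases", {
  one <- pca_reduce(matrix(rnorm(10), ncol = 1))
  expect_equal(one$n_components, 1)
  expect_equal(one$explained, 1)

  set.seed(2)
  a <- rnorm(15)
  two <- pca_reduce(cbind(a, 2 * a + 3), 0.95)   # perfectly correlated pair
  expect_equal(two$n_components, 1)

  X <- matrix(rnorm(40), 10, 4)
  full <- pca_reduce(X, 1.0)
  expect_equal(sum(apply(full$scores, 2, stats::var)),
               sum(apply(X, 2, stats::var)), tolerance = 1e-8)

  expect_error(pca_reduce(matrix(1, 5, 3)), "constant")
})

test_that("RFE output is a permutation and collapses to plain RFE without groups", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("ASD", "TD"), 10))
  r <- svm_rfe_cbr(X, y)
  expect_setequal(r, 1:2)

  X5 <- matrix(rnorm(100), 20, 5)
  plain <- svm_rfe_cbr(X5, y, cbr = FALSE)
  no_groups <- svm_rfe_cbr(X5, y, rho_c = 1 + 1e-9, cbr = TRUE)
  expect_identical(plain, no_groups)
  expect_setequal(plain, 1:5)

  expect_error(svm_rfe_cbr(X5, factor(rep("ASD", 20), levels = c("ASD", "TD"))),
               "both classes")
})

test_that("RFE keeps a planted informative feature and CBR protects duplicates", {
  top <- integer(10)
  for (s in 1:10) {
    set.seed(s)
    y <- factor(rep(c("ASD", "TD"), each = 20))
    X <- matrix(rnorm(200), 40, 5)
    X[, 1] <- X[, 1] + ifelse(y == "ASD", 1.5, -1.5)
    top[s] <- svm_rfe_cbr(X, y, cost = 10, gamma = 1 / 5)[1]
  }
  expect_gte(sum(top == 1), 9)

  # shared importance across near-duplicates: paired CBR on/off comparison
  on <- off <- integer(15)
  for (s in 1:15) {
    set.seed(100 + s)
    y <- factor(rep(c("ASD", "TD"), each = 20))
    noise <- matrix(rnorm(160), 40, 4)
    inf <- rnorm(40) + ifelse(y == "ASD", 0.8, -0.8)
    Xd <- cbind(matrix(rep(inf, 4), 40), noise)
    on[s] <- min(svm_rfe_cbr(Xd, y, cost = 10, gamma = 1 / 8, cbr = TRUE)[1:4])
    off[s] <- min(svm_rfe_cbr(Xd, y, cost = 10, gamma = 1 / 8, cbr = FALSE)[1:4])
  }
  expect_lte(mean(on), mean(off))   # eliminating by group removes the bias
  expect_gte(mean(on == 1), 0.6)    # a duplicate still heads the ranking
})

test_that("confusion metrics reproduce published row arithmetic", {
  # an unbalanced 22/25 split: counts (10, 12, 23, 2)
  m <- confusion_metrics(10, 12, 23, 2)
  expect_equal(m$accuracy, 33 / 47)
  expect_equal(round(100 * m$accuracy, 2), 70.21)
  expect_equal(round(100 * m$tpr, 2), 45.45)
  expect_equal(m$tnr, 0.92)
  expect_equal(m$kappa, 412 / 1070, tolerance = 1e-12)
  expect_equal(round(m$kappa, 2), 0.39)

  perfect <- confusion_metrics(22, 0, 25, 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  all_td <- confusion_metrics(0, 22, 25, 0)
  expect_equal(all_td$kappa, 0)
  expect_equal(all_td$tpr, 0)

  empty_pos <- confusion_metrics(0, 0, 5, 1)
  expect_true(is.na(empty_pos$tpr))
})

test_that("confusion counts reconstruct from class-wise rates", {
  m <- reconstruct_confusion(45.45, 92.00, 22, 25)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(10, 12, 23, 2))
  m2 <- reconstruct_confusion(1.0, 0.8, 22, 25)   # proportions work too
  expect_equal(c(m2$tp, m2$fp), c(22, 5))
})

test_that("the LOSO fit is reproducible, one fold per subject, self-consistent", {
  ch <- tiny_cohort(seed = 33, n_asd = 5, n_td = 6, duration_factor = 0.05,
                    effect_map = effect_preset("reported"))
  tab <- build_feature_table(ch, joints = "head", segments = "V")
  cfg <- classifier_config(seed = 2, top_k_max = 3)
  fit1 <- loso_svm(tab, cfg)
  fit2 <- loso_svm(tab, cfg)

  expect_equal(nrow(fit1$folds), 11)         # one fold per subject
  expect_identical(fit1$folds, fit2$folds)
  expect_identical(fit1$search, fit2$search)
  expect_identical(fit1$metrics, fit2$metrics)

  m <- fit1$metrics
  n <- nrow(tab$values)
  expect_equal(m$accuracy * n, m$tp + m$tn)  # exact rational accuracy
  re <- confusion_metrics(m$tp, m$fn, m$tn, m$fp)
  expect_equal(re$kappa, m$kappa, tolerance = 1e-12)
  expect_lte(fit1$selected$k, fit1$n_pca)
  expect_true(all(fit1$selected$cost %in% cfg$grid,
                  fit1$selected$gamma %in% cfg$grid))

  # fold normalization statistics come from the training subjects alone
  f <- 4
  p <- fit1$pca
  tr <- p$scores[-f, seq_len(fit1$n_pca), drop = FALSE]
  expect_equal(fit1$fold_stats[[f]]$center, apply(tr, 2, stats::median))

  # predict() applies the fitted pipeline to raw features
  pred <- predict(fit1, tab)
  expect_s3_class(pred, "factor")
  expect_length(pred, n)
})

test_that("the strong-effect head model is recovered nearly perfectly", {
  ch <- tiny_cohort(seed = 51, n_asd = 8, n_td = 8, duration_factor = 0.05,
                    effect_map = effect_preset("reported"))
  tab <- build_feature_table(ch, joints = "head",
                             segments = c("V", "VA", "VAO"))
  fit <- loso_svm(tab, classifier_config(seed = 4))
  expect_gte(fit$metrics$kappa, 0.8)
})
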