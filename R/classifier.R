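# LOSO-validated ASD/TD classification stack: PCA reduction, in-fold
# median/MAD normalization, Gaussian C-SVM grid search, nonlinear SVM-RFE
# with correlation-bias reduction, median-rank aggregation, and
# kappa-optimized model selection.

#' Logarithmically spaced hyperparameter grid
#'
#' Geometric sequence from `lo` to `hi` inclusive; the default is the
#' seven-value grid on `[0.1, 1000]` used for both the SVM cost and the
#' Gaussian-kernel gamma.
#'
#' @param lo,hi Positive endpoints, `hi > lo`.
#' @param k Number of values (>= 2).
#' @return Numeric vector of length `k`.
#' @export
#' @examples
#' log_grid() # 0.1, ~0.464, ~2.15, 10, ~46.4, ~215, 1000
log_grid <- function(lo = 0.1, hi = 1000, k = 7) {
  if (!(lo > 0 && hi > lo && k >= 2)) stop("need 0 < lo < hi and k >= 2")
  exp(seq(log(lo), log(hi), length.out = k))
}

#' Median/MAD column normalization with train/apply split
#'
#' Normalizes each column as `(x - median) / MAD`, with the median and the
#' raw median absolute deviation (no normal-consistency factor) computed on
#' the training rows only; validation rows are normalized with the training
#' statistics. Columns with `MAD = 0` are centered but not scaled, and
#' flagged.
#'
#' @param train Numeric matrix of training rows.
#' @param newdata Optional matrix of rows to normalize with the training
#'   statistics.
#' @return List with `train`, `newdata` (or `NULL`), `center`, `scale`
#'   (the raw MADs; 1 is substituted where MAD = 0), `mad_zero` (logical
#'   per column).
#' @export
robust_normalize <- function(train, newdata = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 1)
  center <- apply(train, 2, stats::median)
  mad_raw <- apply(train, 2, function(v) stats::median(abs(v - stats::median(v))))
  mad_zero <- mad_raw == 0
  scale <- ifelse(mad_zero, 1, mad_raw)
  norm1 <- function(m) sweep(sweep(as.matrix(m), 2, center), 2, scale, "/")
  list(train = norm1(train),
       newdata = if (!is.null(newdata)) norm1(newdata),
       center = center, scale = scale, mad_zero = mad_zero)
}

#' PCA reduction to a target explained-variance fraction
#'
#' Centers columns, computes principal components, and keeps the smallest
#' number of components whose cumulative explained-variance ratio reaches
#' `variance_fraction`. Component signs follow a deterministic convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param X Numeric matrix (>= 2 rows).
#' @param variance_fraction Target in (0, 1] (default 0.95).
#' @return List with `scores` (n x n_components), `loadings` (d x
#'   n_components), `center`, `n_components`, `explained` (per-component
#'   variance ratios, all components).
#' @export
pca_reduce <- function(X, variance_fraction = 0.95) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, variance_fraction > 0, variance_fraction <= 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total == 0) stop("all columns are constant; PCA undefined")
  explained <- pc$sdev^2 / total
  ncomp <- which(cumsum(explained) >= variance_fraction - 1e-12)[1]
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  list(scores = scores[, seq_len(ncomp), drop = FALSE],
       loadings = rot[, seq_len(ncomp), drop = FALSE],
       center = pc$center, n_components = ncomp, explained = explained)
}

# Squared-distance matrices per feature (list) and their sum, over rows of X.
pairwise_sqdist <- function(X) {
  per <- lapply(seq_len(ncol(X)), function(j) outer(X[, j], X[, j], "-")^2)
  list(per = per, total = Reduce(`+`, per))
}

# Connected components of the |r| >= rho_c correlation graph, as a list of
# integer index vectors.
correlation_groups <- function(X, rho_c) {
  d <- ncol(X)
  if (d <= 1) return(as.list(seq_len(d)))
  sds <- apply(X, 2, stats::sd)
  cm <- matrix(0, d, d)
  ok <- sds > 0
  if (sum(ok) >= 2)
    cm[ok, ok] <- suppressWarnings(abs(stats::cor(X[, ok, drop = FALSE])))
  adj <- cm >= rho_c
  diag(adj) <- TRUE
  comp <- integer(d); cur <- 0L
  for (i in seq_len(d)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  split(seq_len(d), comp)
}

#' Nonlinear SVM-RFE ranking with correlation-bias reduction
#'
#' Recursive feature elimination driven by the Gaussian-kernel SVM cost
#' function: at each step a C-SVM is trained on the surviving features and
#' each feature `i` is scored by the change in the dual objective when it
#' is removed at fixed dual coefficients,
#' `DJ(i) = 1/2 a'Ha - 1/2 a'H(-i)a`, where `H` is the label-signed kernel
#' matrix over support vectors and `H(-i)` recomputes the kernel without
#' feature `i`. The feature whose removal changes the objective least
#' (smallest `|DJ|`) is eliminated; the last survivor gets rank 1.
#'
#' Correlation-bias reduction (CBR): features whose pairwise `|Pearson r|`
#' on the training data reaches `rho_c` form groups (connected components),
#' and each member's criterion is computed by removing the whole group, so
#' importance shared across near-duplicates is not underestimated.
#'
#' @param X Training feature matrix.
#' @param y Two-level factor of class labels.
#' @param cost,gamma C-SVM hyperparameters (default cost 10 — the grid
#'   midpoint — and gamma `1/ncol(X)`).
#' @param rho_c Correlation threshold for CBR grouping (default 0.9); any
#'   value > 1 disables grouping.
#' @param cbr Apply correlation-bias reduction (default `TRUE`).
#' @return Integer vector of ranks (length `ncol(X)`, a permutation of
#'   `1..d`; rank 1 = most important, i.e., eliminated last).
#' @export
svm_rfe_cbr <- function(X, y, cost = 10, gamma = NULL, rho_c = 0.9,
                        cbr = TRUE) {
  X <- as.matrix(X)
  y <- as.factor(y)
  d <- ncol(X)
  stopifnot(d >= 2)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  if (is.null(gamma)) gamma <- 1 / d
  rank <- integer(d)
  remaining <- seq_len(d)
  next_rank <- d
  while (length(remaining) > 1) {
    Xc <- X[, remaining, drop = FALSE]
    fit <- e1071::svm(Xc, y, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    sv <- Xc[fit$index, , drop = FALSE]
    a <- as.numeric(fit$coefs)     # alpha_i * y_i for support vectors
    sq <- pairwise_sqdist(sv)
    K <- exp(-gamma * sq$total)
    J <- 0.5 * drop(crossprod(a, K %*% a))
    groups <- if (cbr) {
      correlation_groups(Xc, rho_c)
    } else {
      as.list(seq_along(remaining))
    }
    dj <- numeric(length(remaining))
    for (g in groups) {
      Dg <- Reduce(`+`, sq$per[g])
      K_minus <- K * exp(gamma * Dg)   # kernel without the group's features
      dj[g] <- J - 0.5 * drop(crossprod(a, K_minus %*% a))
    }
    drop_local <- which.min(abs(dj))   # smallest |change|; ties: lowest index
    rank[remaining[drop_local]] <- next_rank
    next_rank <- next_rank - 1L
    remaining <- remaining[-drop_local]
  }
  rank[remaining] <- 1L
  rank
}

#' Classification metrics from confusion counts
#'
#' ASD is the positive class. Accuracy `(TP+TN)/N`, sensitivity
#' `TPR = TP/(TP+FN)`, specificity `TNR = TN/(TN+FP)`, and Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with the chance agreement `p_e` from the
#' marginal products.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts (TP+FN = n ASD,
#'   TN+FP = n TD).
#' @return List with `tp`, `fn`, `tn`, `fp`, `accuracy`, `tpr`, `tnr`,
#'   `kappa` (rates as proportions in \[0, 1\]; `tpr`/`tnr` are `NA` when
#'   the class is empty).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  n <- tp + fn + tn + fp
  if (n == 0) stop("empty confusion matrix")
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) NA_real_ else (po - pe) / (1 - pe)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = po,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       kappa = kappa)
}

#' Reconstruct confusion counts from class-wise rates
#'
#' Given a reported sensitivity and specificity and the two group sizes,
#' recovers the integer confusion counts (`TP = round(TPR * n_pos)` etc.)
#' and recomputes all metrics from them — useful for checking the internal
#' consistency of published per-model results.
#'
#' @param tpr,tnr Reported rates, as proportions or percentages (values
#'   > 1 are treated as percentages).
#' @param n_pos,n_neg Group sizes (default 22 ASD / 25 TD).
#' @return As [confusion_metrics()].
#' @export
#' @examples
#' # TPR 45.45%, TNR 92.00% with 22/25 subjects
#' m <- reconstruct_confusion(45.45, 92.00)
#' round(100 * m$accuracy, 2); round(m$kappa, 2)
reconstruct_confusion <- function(tpr, tnr, n_pos = 22, n_neg = 25) {
  if (tpr > 1) tpr <- tpr / 100
  if (tnr > 1) tnr <- tnr / 100
  stopifnot(tpr >= 0, tpr <= 1, tnr >= 0, tnr <= 1, n_pos > 0, n_neg > 0)
  tp <- round(tpr * n_pos)
  tn <- round(tnr * n_neg)
  confusion_metrics(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' Classifier stack configuration
#'
#' @param variance_fraction PCA explained-variance target (default 0.95).
#' @param grid_lo,grid_hi,grid_k Hyperparameter grid: `grid_k` values
#'   log-spaced on `[grid_lo, grid_hi]`, shared by cost and gamma
#'   (default 7 on \[0.1, 1000\], i.e., 49 pairs).
#' @param pca_scope `"global"` (PCA on the full table before the LOSO
#'   loop, the replication default) or `"per_fold"` (leakage-free
#'   variant: PCA refit inside each training fold).
#' @param rfe Run SVM-RFE feature ranking (default `TRUE`; when `FALSE`
#'   the natural PCA component order is used).
#' @param cbr Correlation-bias reduction inside RFE (default `TRUE`).
#' @param rho_c CBR correlation threshold (default 0.9).
#' @param rfe_cost,rfe_gamma Hyperparameters of the SVM used for RFE
#'   ranking (defaults: cost 10, the grid midpoint; gamma `1/n_features`).
#' @param top_k_max Largest feature-subset size searched during model
#'   selection (default 10; capped at the number of PCA components).
#' @param seed RNG seed recorded with the fit.
#' @return An object of class `"classifier_config"`.
#' @export
classifier_config <- function(variance_fraction = 0.95,
                              grid_lo = 0.1, grid_hi = 1000, grid_k = 7,
                              pca_scope = c("global", "per_fold"),
                              rfe = TRUE, cbr = TRUE, rho_c = 0.9,
                              rfe_cost = 10, rfe_gamma = NULL,
                              top_k_max = 10, seed = 1L) {
  pca_scope <- match.arg(pca_scope)
  stopifnot(variance_fraction > 0, variance_fraction <= 1,
            rho_c > 0, top_k_max >= 1)
  structure(
    list(variance_fraction = variance_fraction,
         grid = log_grid(grid_lo, grid_hi, grid_k),
         pca_scope = pca_scope, rfe = rfe, cbr = cbr, rho_c = rho_c,
         rfe_cost = rfe_cost, rfe_gamma = rfe_gamma,
         top_k_max = as.integer(top_k_max), seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Fit the LOSO-validated SVM classification stack
#'
#' The full supervised pipeline on a feature table: PCA to the
#' explained-variance target (global by default), then leave-one-subject-out
#' cross-validation in which each training fold is median/MAD-normalized
#' (the held-out subject is normalized with the training statistics),
#' ranked by nonlinear SVM-RFE with correlation-bias reduction, and
#' classified by a Gaussian C-SVM. Feature ranks are aggregated across
#' folds by their median; every top-k subset of the aggregated ranking is
#' then evaluated over the full cost x gamma grid by LOSO confusion
#' metrics, and the configuration with the best Cohen's kappa is reported
#' (ties broken by fewer features, higher accuracy, smaller cost, smaller
#' gamma).
#'
#' @param table A `"feature_table"`.
#' @param config A [classifier_config()].
#' @return An object of class `"loso_svm"`: a list with `metrics`
#'   (confusion counts and rates), `selected` (`k`, `cost`, `gamma`),
#'   `n_pca`, `folds` (per-subject true/predicted labels), `fold_stats`
#'   (per-fold normalization center/scale), `median_rank`,
#'   `rfe_ranks` (folds x features), `feature_order`, `search` (kappa per
#'   candidate), `pca`, `normalization` (full-data median/MAD), `final_model`
#'   (SVM refit on all subjects at the chosen configuration), `config`,
#'   `table_info`.
#' @export
loso_svm <- function(table, config = classifier_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "classifier_config"))
  set.seed(config$seed)
  X <- table$values
  y <- factor(table$subjects$group, levels = c("ASD", "TD"))
  n <- nrow(X)
  if (any(table(y) < 2)) stop("need >= 2 subjects per class")

  global_pca <- config$pca_scope == "global"
  pca <- if (global_pca) pca_reduce(X, config$variance_fraction) else NULL

  # Per-fold prepared matrices: normalized training scores + test row.
  folds <- vector("list", n)
  for (f in seq_len(n)) {
    if (global_pca) {
      tr_scores <- pca$scores[-f, , drop = FALSE]
      te_scores <- pca$scores[f, , drop = FALSE]
    } else {
      p <- pca_reduce(X[-f, , drop = FALSE], config$variance_fraction)
      tr_scores <- p$scores
      te_scores <- (X[f, , drop = FALSE] -
                      matrix(p$center, 1)) %*% p$loadings
    }
    nz <- robust_normalize(tr_scores, te_scores)
    folds[[f]] <- list(train = nz$train, test = nz$newdata,
                       y = y[-f], m = ncol(tr_scores),
                       center = nz$center, scale = nz$scale)
  }
  m <- min(vapply(folds, `[[`, integer(1) + 0, "m"))
  if (m < 1) stop("no PCA components retained")

  # Per-fold RFE rankings, aggregated by median rank.
  if (config$rfe && m >= 2) {
    rfe_ranks <- t(vapply(folds, function(fd)
      svm_rfe_cbr(fd$train[, seq_len(m), drop = FALSE], fd$y,
                  cost = config$rfe_cost, gamma = config$rfe_gamma,
                  rho_c = if (config$cbr) config$rho_c else Inf,
                  cbr = config$cbr),
      integer(m)))
    median_rank <- apply(rfe_ranks, 2, stats::median)
  } else {
    rfe_ranks <- matrix(rep(seq_len(m), each = n), nrow = n)
    median_rank <- seq_len(m)
  }
  feature_order <- order(median_rank, seq_len(m))

  # Kappa-optimized search over top-k subsets and the 49-point grid.
  grid <- config$grid
  k_max <- min(m, config$top_k_max)
  search <- expand.grid(k = seq_len(k_max), cost = grid, gamma = grid,
                        KEEP.OUT.ATTRS = FALSE)
  search$kappa <- NA_real_; search$accuracy <- NA_real_
  preds <- matrix(NA_character_, nrow = nrow(search), ncol = n)
  for (k in seq_len(k_max)) {
    sel <- feature_order[seq_len(k)]
    rows_k <- which(search$k == k)
    for (f in seq_len(n)) {
      Xtr <- folds[[f]]$train[, sel, drop = FALSE]
      Xte <- folds[[f]]$test[, sel, drop = FALSE]
      ytr <- folds[[f]]$y
      for (r in rows_k) {
        fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = search$cost[r],
                          gamma = search$gamma[r], scale = FALSE)
        preds[r, f] <- as.character(predict(fit, Xte))
      }
    }
  }
  truth <- as.character(y)
  for (r in seq_len(nrow(search))) {
    cm <- confusion_from_labels(truth, preds[r, ])
    search$kappa[r] <- cm$kappa
    search$accuracy[r] <- cm$accuracy
  }
  ord <- order(-search$kappa, search$k, -search$accuracy,
               search$cost, search$gamma)
  best <- search[ord[1], ]

  sel <- feature_order[seq_len(best$k)]
  best_preds <- preds[ord[1], ]
  metrics <- confusion_from_labels(truth, best_preds)

  # Final model on all subjects at the chosen configuration, for predict().
  full_scores <- if (global_pca) pca$scores else {
    p <- pca_reduce(X, config$variance_fraction)
    pca <- p
    p$scores
  }
  nz_full <- robust_normalize(full_scores[, seq_len(m), drop = FALSE])
  final_model <- e1071::svm(nz_full$train[, sel, drop = FALSE], y,
                            kernel = "radial", cost = best$cost,
                            gamma = best$gamma, scale = FALSE)

  structure(
    list(metrics = metrics,
         selected = list(k = best$k, cost = best$cost, gamma = best$gamma),
         n_pca = m,
         folds = data.frame(subject_id = table$subjects$subject_id,
                            true = truth, predicted = best_preds,
                            cost = best$cost, gamma = best$gamma,
                            stringsAsFactors = FALSE),
         fold_stats = lapply(folds, function(fd)
           list(center = fd$center, scale = fd$scale)),
         median_rank = median_rank,
         rfe_ranks = rfe_ranks,
         feature_order = feature_order,
         search = search,
         pca = pca,
         normalization = list(center = nz_full$center, scale = nz_full$scale,
                              mad_zero = nz_full$mad_zero),
         final_model = final_model,
         config = config,
         table_info = list(columns = table$columns,
                           n_asd = sum(truth == "ASD"),
                           n_td = sum(truth == "TD"))),
    class = "loso_svm"
  )
}

confusion_from_labels <- function(truth, pred) {
  confusion_metrics(
    tp = sum(truth == "ASD" & pred == "ASD"),
    fn = sum(truth == "ASD" & pred == "TD"),
    tn = sum(truth == "TD" & pred == "TD"),
    fp = sum(truth == "TD" & pred == "ASD")
  )
}

#' @export
print.loso_svm <- function(x, ...) {
  m <- x$metrics
  cat("LOSO-validated Gaussian C-SVM (ASD vs TD)\n")
  cat(sprintf("  subjects: %d ASD / %d TD; PCA components: %d; selected features: %d/%d\n",
              x$table_info$n_asd, x$table_info$n_td, x$n_pca,
              x$selected$k, x$n_pca))
  cat(sprintf("  chosen cost = %.4g, gamma = %.4g\n",
              x$selected$cost, x$selected$gamma))
  cat(sprintf("  accuracy %.2f%%  TPR %.2f%%  TNR %.2f%%  kappa %.2f\n",
              100 * m$accuracy, 100 * m$tpr, 100 * m$tnr, m$kappa))
  invisible(x)
}

#' @export
summary.loso_svm <- function(object, ...) {
  m <- object$metrics
  out <- list(
    confusion = matrix(c(m$tp, m$fp, m$fn, m$tn), 2, 2,
                       dimnames = list(predicted = c("ASD", "TD"),
                                       true = c("ASD", "TD"))),
    metrics = m,
    selected = object$selected,
    n_pca = object$n_pca,
    median_rank = object$median_rank
  )
  class(out) <- "summary.loso_svm"
  out
}

#' @export
print.summary.loso_svm <- function(x, ...) {
  cat("Confusion matrix (LOSO):\n")
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("\naccuracy %.2f%%  TPR %.2f%%  TNR %.2f%%  kappa %.3f\n",
              100 * m$accuracy, 100 * m$tpr, 100 * m$tnr, m$kappa))
  cat(sprintf("features selected: %d of %d PCA components (cost %.4g, gamma %.4g)\n",
              x$selected$k, x$n_pca, x$selected$cost, x$selected$gamma))
  cat("median RFE rank per component:", paste(x$median_rank, collapse = " "), "\n")
  invisible(x)
}

#' Predict group labels for new subjects
#'
#' Applies the fitted pipeline (full-data PCA projection, median/MAD
#' normalization, selected components, final SVM) to new raw feature rows.
#'
#' @param object A `"loso_svm"` fit.
#' @param newdata A `"feature_table"` or a numeric matrix whose columns
#'   match the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels (`ASD`/`TD`).
#' @export
predict.loso_svm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  if (ncol(X) != length(object$pca$center))
    stop("newdata must have ", length(object$pca$center), " feature columns")
  scores <- (X - matrix(object$pca$center, nrow(X), ncol(X), byrow = TRUE)) %*%
    object$pca$loadings
  scores <- scores[, seq_len(object$n_pca), drop = FALSE]
  z <- sweep(sweep(scores, 2, object$normalization$center), 2,
             object$normalization$scale, "/")
  sel <- object$feature_order[seq_len(object$selected$k)]
  predict(object$final_model, z[, sel, drop = FALSE])
}
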