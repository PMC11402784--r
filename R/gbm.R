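# Gradient-boosted stability classifier: stratified 75/25 split, repeated
# k-fold cross-validated grid search maximizing AUROC, hold-out evaluation,
# and two flavors of feature importance (ensemble relative influence and
# permutation AUROC drop). xgboost provides the boosted trees behind this
# surface; the harness (split, grid, CV scheme, importances) is the contract.

#' Grid of boosting hyperparameters
#'
#' The full grid spans the complete reference search (interaction depth 1/3/6,
#' 1-500 trees, shrinkage 0.001-0.1, minimum terminal-node size 10); the
#' reduced default keeps desk-scale runtime.
#'
#' @param full use the full reference grid instead of the reduced default.
#' @return tibble with `depth`, `n_trees`, `shrinkage`, `min_node`.
#' @export
gbm_grid <- function(full = FALSE) {
  if (full) {
    tidyr::crossing(
      depth = c(1L, 3L, 6L),
      n_trees = c(1L, seq(10L, 50L, 10L), seq(100L, 500L, 50L)),
      shrinkage = c(0.001, 0.005, 0.01, 0.05, 0.1),
      min_node = 10L
    )
  } else {
    tidyr::crossing(
      depth = c(1L, 3L, 6L),
      n_trees = c(50L, 100L, 200L),
      shrinkage = c(0.01, 0.1),
      min_node = 10L
    )
  }
}

auroc <- function(labels, scores) {
  # labels: 0/1 integer; Mann-Whitney formulation via pROC
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return MCC in `[-1, 1]`; 0 when a marginal is empty.
#' @export
mcc <- function(tp, tn, fp, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

stratified_split <- function(labels, p_train, seed) {
  set.seed(seed)
  idx_train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    n_tr <- round(length(idx) * p_train)
    sample(idx, n_tr)
  }), use.names = FALSE)
  sort(idx_train)
}

xgb_fit <- function(X, y, params, nrounds, seed) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", eval_metric = "auc",
      max_depth = params$depth, eta = params$shrinkage,
      min_child_weight = params$min_node, subsample = 1, colsample_bytree = 1,
      nthread = 1
    ),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = nrounds, verbose = 0
  )
}

#' Train and evaluate the boosted stability classifier
#'
#' Stratified 75/25 train/hold-out split, grid search by repeated
#' fivefold cross-validation on the training portion only (maximizing mean CV
#' AUROC), final refit on the full training portion and a single hold-out
#' evaluation reporting AUROC, accuracy and MCC plus both feature-importance
#' measures. Hold-out rows are never touched by the CV or the grid selection.
#'
#' @param X feature matrix tibble from [build_feature_matrix()] (`gene`,
#'   `label`, features). Both classes need at least 10 members.
#' @param split_seed seed controlling the split, CV folds, boosting and the
#'   permutation shuffles.
#' @param grid hyperparameter grid, default [gbm_grid()].
#' @param cv_folds,cv_repeats cross-validation scheme (default fivefold,
#'   five repeats).
#' @param positive_label label treated as the positive class; default the
#'   lexicographically first label (`decreased` in the standard workflow).
#' @param perm_repeats shuffles per feature for permutation importance.
#' @return a `stability_model` object; see [tidy.stability_model()] and
#'   [glance.stability_model()].
#' @export
train_stability_classifier <- function(X, split_seed = 1, grid = gbm_grid(),
                                       cv_folds = 5, cv_repeats = 5,
                                       positive_label = NULL,
                                       perm_repeats = 10) {
  assert_columns(X, c("gene", "label"))
  classes <- sort(unique(X$label))
  if (length(classes) != 2) abort("exactly 2 classes are required")
  if (any(table(X$label) < 10)) abort("each class needs at least 10 members")
  positive_label <- positive_label %||% classes[1]

  feats <- setdiff(names(X), c("gene", "label"))
  mat <- as.matrix(X[feats])
  y <- as.integer(X$label == positive_label)

  idx_train <- stratified_split(X$label, 0.75, seed = split_seed)
  idx_test <- setdiff(seq_len(nrow(X)), idx_train)

  # CV grid search on the training portion only
  cv_scores <- numeric(nrow(grid))
  cv_sds <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, ]
    aucs <- c()
    for (rep in seq_len(cv_repeats)) {
      set.seed(split_seed * 1000 + rep)
      folds <- make_stratified_folds(y[idx_train], cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- idx_train[folds != f]
        va <- idx_train[folds == f]
        m <- xgb_fit(mat[tr, , drop = FALSE], y[tr], g, g$n_trees,
                     seed = split_seed + gi)
        pred <- predict(m, xgboost::xgb.DMatrix(mat[va, , drop = FALSE]))
        if (length(unique(y[va])) == 2) aucs <- c(aucs, auroc(y[va], pred))
      }
    }
    cv_scores[gi] <- mean(aucs)
    cv_sds[gi] <- sd(aucs)
  }
  best <- grid[which.max(cv_scores), ]

  model <- xgb_fit(mat[idx_train, , drop = FALSE], y[idx_train], best,
                   best$n_trees, seed = split_seed)
  pred_test <- predict(model, xgboost::xgb.DMatrix(mat[idx_test, , drop = FALSE]))
  y_test <- y[idx_test]
  cls <- as.integer(pred_test >= 0.5)
  eval <- list(
    auroc = auroc(y_test, pred_test),
    accuracy = mean(cls == y_test),
    mcc = mcc(sum(cls == 1 & y_test == 1), sum(cls == 0 & y_test == 0),
              sum(cls == 1 & y_test == 0), sum(cls == 0 & y_test == 1))
  )

  rel_inf <- relative_influence(model, feats)
  perm <- permutation_importance_matrix(model, mat[idx_test, , drop = FALSE],
                                        y_test, eval$auroc,
                                        r = perm_repeats, seed = split_seed)

  structure(
    list(
      model = model, features = feats, positive_label = positive_label,
      classes = classes, best_params = as.list(best),
      cv = bind_cols(grid, tibble(cv_auroc = cv_scores, cv_sd = cv_sds)),
      cv_sd_best = cv_sds[which.max(cv_scores)],
      eval = eval,
      importance = left_join(rel_inf, perm, by = "feature"),
      idx_train = idx_train, idx_test = idx_test, genes = X$gene,
      split_seed = split_seed
    ),
    class = "stability_model"
  )
}

make_stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

relative_influence <- function(model, feats) {
  imp <- xgboost::xgb.importance(model = model, feature_names = feats)
  tibble(feature = feats) %>%
    left_join(tibble(feature = imp$Feature, relative_influence = 100 * imp$Gain),
              by = "feature") %>%
    mutate(relative_influence = dplyr::coalesce(.data$relative_influence, 0))
}

permutation_importance_matrix <- function(model, X_test, y_test, base_auroc,
                                          r = 10, seed = 1) {
  set.seed(seed)
  drops <- vapply(seq_len(ncol(X_test)), function(j) {
    mean(vapply(seq_len(r), function(i) {
      Xp <- X_test
      Xp[, j] <- sample(Xp[, j])
      if (stats::var(X_test[, j]) == 0) return(0)
      base_auroc - auroc(y_test, predict(model, xgboost::xgb.DMatrix(Xp)))
    }, numeric(1)))
  }, numeric(1))
  tibble(feature = colnames(X_test), permutation_importance = drops)
}

#' Feature importance of a trained stability model
#'
#' Relative influence from the boosted ensemble and permutation importance
#' (mean hold-out AUROC drop over `r` seeded shuffles of each feature column).
#' Both are computed at training time; this accessor recomputes the
#' permutation measure on a supplied test matrix if given.
#'
#' @param model a `stability_model`.
#' @param X_test optional feature tibble to recompute permutation importance on.
#' @param r shuffles per feature.
#' @return tibble with `feature`, `relative_influence`,
#'   `permutation_importance`.
#' @export
feature_importance <- function(model, X_test = NULL, r = 10) {
  stopifnot(inherits(model, "stability_model"))
  if (is.null(X_test)) return(model$importance)
  assert_columns(X_test, c("label"))
  mat <- as.matrix(X_test[model$features])
  y <- as.integer(X_test$label == model$positive_label)
  base <- auroc(y, predict(model$model, xgboost::xgb.DMatrix(mat)))
  perm <- permutation_importance_matrix(model$model, mat, y, base, r = r,
                                        seed = model$split_seed)
  left_join(relative_influence(model$model, model$features), perm, by = "feature")
}

#' @export
print.stability_model <- function(x, ...) {
  cat("<stability_model>\n")
  cat(sprintf("  features: %d | train/test: %d/%d | positive: %s\n",
              length(x$features), length(x$idx_train), length(x$idx_test),
              x$positive_label))
  cat(sprintf("  best: depth=%d trees=%d shrinkage=%g\n",
              x$best_params$depth, x$best_params$n_trees, x$best_params$shrinkage))
  cat(sprintf("  hold-out AUROC=%.3f accuracy=%.3f MCC=%.3f\n",
              x$eval$auroc, x$eval$accuracy, x$eval$mcc))
  invisible(x)
}

#' Tidy the feature importances of a stability model
#' @method tidy stability_model
#' @param x a `stability_model`.
#' @param ... unused.
#' @return tibble with one row per feature, both importance measures, ordered
#'   by relative influence.
#' @export
tidy.stability_model <- function(x, ...) {
  x$importance %>% arrange(desc(.data$relative_influence))
}

#' One-row hold-out summary of a stability model
#' @method glance stability_model
#' @param x a `stability_model`.
#' @param ... unused.
#' @return tibble with `auroc`, `accuracy`, `mcc`, chosen hyperparameters and
#'   split sizes.
#' @export
glance.stability_model <- function(x, ...) {
  tibble(
    auroc = x$eval$auroc, accuracy = x$eval$accuracy, mcc = x$eval$mcc,
    depth = x$best_params$depth, n_trees = x$best_params$n_trees,
    shrinkage = x$best_params$shrinkage,
    n_train = length(x$idx_train), n_test = length(x$idx_test)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
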