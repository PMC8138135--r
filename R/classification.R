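#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals indices round-robin, so each
#' fold's class ratio matches the cohort's within one sample.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_stratified_folds <- function(y, k = 10) {
  n <- length(y)
  if (n < k) stop("need at least k observations", call. = FALSE)
  folds <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Train a linear-kernel SVM
#'
#' Margin-maximizing linear SVM (penalty `C`) over e1071/libsvm. Features
#' are expected to be standardized by the caller; decision scores are
#' oriented so that positive means "case" (label 1).
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (1 = case, 0 = control).
#' @param C Soft-margin penalty (default 1).
#' @return List of class `linear_svm` wrapping the fitted model.
#' @export
train_svm <- function(X, y, C = 1) {
  if (length(unique(y)) < 2) stop("single-class response", call. = FALSE)
  X <- as.matrix(X)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                    kernel = "linear", cost = C, scale = FALSE)
  out <- list(fit = fit,
              flip = identical(colnames(attr(
                stats::predict(fit, X[1, , drop = FALSE],
                               decision.values = TRUE),
                "decision.values")), "0/1"))
  class(out) <- "linear_svm"
  out
}

#' Decision scores of a linear SVM
#'
#' @param model A `linear_svm`.
#' @param X Feature matrix (same standardization as training).
#' @return Numeric signed scores, positive = case.
#' @export
decision_scores <- function(model, X) {
  d <- attr(stats::predict(model$fit, as.matrix(X), decision.values = TRUE),
            "decision.values")
  s <- as.numeric(d)
  if (model$flip) -s else s
}

#' Area under the ROC curve (midrank / Wilcoxon form)
#'
#' AUC as the probability that a random case outranks a random control by
#' decision score; ties are handled by midranks.
#'
#' @param scores Numeric decision scores, larger = more case-like.
#' @param y Binary labels (1 = case).
#' @return Scalar in [0, 1].
#' @export
auc_score <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1); fp <- cumsum(y[ord] == 0)
  data.frame(fpr = c(0, fp / max(1, sum(y == 0))),
             tpr = c(0, tp / max(1, sum(y == 1))))
}

scale_apply <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
}

#' Cross-validated classifier evaluation
#'
#' Stratified k-fold cross-validation of the linear SVM. Standardization
#' (z-score) is fitted on each training fold only. Per fold: sensitivity =
#' TP/(TP+FN) with "case" positive, specificity = TN/(TN+FP), and AUC from
#' the decision scores; the report carries per-fold values, their means, and
#' ROC points from the pooled out-of-fold scores (for plotting only).
#'
#' @param X Feature matrix (participants x features).
#' @param y Binary labels (1 = case).
#' @param k Folds (default 10).
#' @param C SVM penalty.
#' @param folds Optional precomputed fold ids (for identical fold assignment
#'   across feature sets); default stratified from the current RNG state.
#' @param standardize Per-fold z-scoring of every feature (default TRUE).
#'   Set FALSE for inputs already on a meaningful common scale, e.g.
#'   principal-component scores, where re-inflating near-zero-variance
#'   components would drown the signal; features are then only centered.
#' @return List of class `classifier_report`: `per_fold` (data.frame),
#'   `mean_sensitivity`, `mean_specificity`, `mean_auc`, `mean_accuracy`,
#'   `roc`, `selected_features`.
#' @export
crossval_evaluate <- function(X, y, k = 10, C = 1, folds = NULL,
                              standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(table(y)) < k) {
    stop("cannot stratify: a class has fewer than k members", call. = FALSE)
  }
  if (is.null(folds)) folds <- make_stratified_folds(y, k)
  pooled_scores <- numeric(length(y))
  rows <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- folds == f
    ctr <- colMeans(X[tr, , drop = FALSE])
    sds <- if (standardize) apply(X[tr, , drop = FALSE], 2, stats::sd)
           else rep(1, ncol(X))
    Xtr <- scale_apply(X[tr, , drop = FALSE], ctr, sds)
    Xte <- scale_apply(X[te, , drop = FALSE], ctr, sds)
    m <- train_svm(Xtr, y[tr], C = C)
    sc <- decision_scores(m, Xte)
    pooled_scores[te] <<- sc
    pred <- as.integer(sc > 0)
    tp <- sum(pred == 1 & y[te] == 1); fn <- sum(pred == 0 & y[te] == 1)
    tn <- sum(pred == 0 & y[te] == 0); fp <- sum(pred == 1 & y[te] == 0)
    data.frame(fold = f, tp = tp, fn = fn, tn = tn, fp = fp,
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
               accuracy = (tp + tn) / (tp + tn + fp + fn),
               auc = auc_score(sc, y[te]))
  })
  per_fold <- do.call(rbind, rows)
  out <- list(per_fold = per_fold,
              mean_sensitivity = mean(per_fold$sensitivity),
              mean_specificity = mean(per_fold$specificity),
              mean_accuracy = mean(per_fold$accuracy),
              mean_auc = mean(per_fold$auc),
              roc = roc_points(pooled_scores, y),
              selected_features = colnames(X))
  class(out) <- "classifier_report"
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %d features, %d folds: sens %.3f, spec %.3f, AUC %.3f\n",
    length(x$selected_features), nrow(x$per_fold),
    x$mean_sensitivity, x$mean_specificity, x$mean_auc))
  invisible(x)
}

#' Mean cross-validated accuracy (SBS evaluator)
#'
#' @inheritParams crossval_evaluate
#' @return Scalar mean fold accuracy.
#' @export
cv_accuracy <- function(X, y, k = 10, C = 1, folds = NULL) {
  crossval_evaluate(X, y, k = k, C = C, folds = folds)$mean_accuracy
}

#' Sequential backward selection
#'
#' Greedy backward elimination: starting from the full feature set, at each
#' step the feature whose removal maximizes the evaluation measure is
#' dropped, provided the measure does not fall below its current value (ties
#' favor the smaller set); the search stops when every possible removal
#' would lower the measure, or when one feature remains.
#'
#' @param X Feature matrix with column names.
#' @param y Binary labels.
#' @param evaluator Function(X, y) -> scalar; default mean k-fold CV
#'   accuracy of the linear SVM on a fold assignment fixed at entry (so the
#'   search is deterministic given the RNG state).
#' @param k,C Passed to the default evaluator.
#' @return Character vector of retained feature names.
#' @export
sbs_select <- function(X, y, evaluator = NULL, k = 10, C = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("SBS needs >= 2 features", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(evaluator)) {
    folds <- make_stratified_folds(y, k)
    evaluator <- function(Xs, ys) cv_accuracy(Xs, ys, k = k, C = C,
                                              folds = folds)
  }
  keep <- colnames(X)
  cur <- evaluator(X[, keep, drop = FALSE], y)
  while (length(keep) > 1) {
    evals <- vapply(keep, function(f) {
      evaluator(X[, setdiff(keep, f), drop = FALSE], y)
    }, numeric(1))
    best <- which.max(evals)
    if (evals[best] >= cur) {
      keep <- setdiff(keep, keep[best])
      cur <- evals[best]
    } else {
      break
    }
  }
  keep
}

block_combinations <- function() {
  list(
    spatiotemporal = "spatiotemporal",
    time = "time",
    frequency = "frequency",
    `spatiotemporal+time` = c("spatiotemporal", "time"),
    `spatiotemporal+frequency` = c("spatiotemporal", "frequency"),
    `time+frequency` = c("time", "frequency"),
    all = c("spatiotemporal", "time", "frequency")
  )
}

#' Evaluate all seven feature-block combinations
#'
#' Runs the cross-validated linear SVM on every nonempty subset of the three
#' feature banks, with an identical fold assignment across combinations so
#' the rows are comparable. Optionally applies sequential backward selection
#' to each combination first.
#'
#' @param blocks Named list with matrices `spatiotemporal`, `time`,
#'   `frequency` (same participants, same row order).
#' @param y Binary labels (1 = case).
#' @param k,C Cross-validation folds and SVM penalty.
#' @param sbs Run [sbs_select()] per combination first (default FALSE).
#' @param seed Optional seed fixing fold assignment (and SBS determinism).
#' @param standardize Passed to [crossval_evaluate()]. When FALSE, each
#'   block is first normalized to unit total variance so no block dominates
#'   a concatenation by gross scale alone.
#' @return Named list of 7 `classifier_report`s, each with a
#'   `block_combination` element, in the canonical order: the three single
#'   blocks, the three pairs, then all features.
#' @export
run_block_combinations <- function(blocks, y, k = 10, C = 1, sbs = FALSE,
                                   seed = NULL, standardize = TRUE) {
  stopifnot(all(c("spatiotemporal", "time", "frequency") %in% names(blocks)))
  if (!is.null(seed)) set.seed(seed)
  if (!standardize) {
    blocks <- lapply(blocks, function(X) {
      X / sqrt(max(sum(apply(X, 2, stats::var)), .Machine$double.eps))
    })
  }
  folds <- make_stratified_folds(y, k)
  out <- lapply(block_combinations(), function(combo) {
    X <- do.call(cbind, blocks[combo])
    if (sbs && ncol(X) >= 2) {
      sel <- sbs_select(X, y, k = k, C = C)
      X <- X[, sel, drop = FALSE]
    }
    rep <- crossval_evaluate(X, y, k = k, C = C, folds = folds,
                             standardize = standardize)
    rep$block_combination <- combo
    rep
  })
  out
}

#' Summarize block-combination reports as a table
#'
#' @param reports List from [run_block_combinations()].
#' @return data.frame with one row per combination: sensitivity,
#'   specificity, AUC (fold means).
#' @export
combination_table <- function(reports) {
  data.frame(
    combination = names(reports),
    sensitivity = vapply(reports, function(r) r$mean_sensitivity, numeric(1)),
    specificity = vapply(reports, function(r) r$mean_specificity, numeric(1)),
    auc = vapply(reports, function(r) r$mean_auc, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
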