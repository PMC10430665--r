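## Random-forest agonist/antagonist classifiers.
##
## Samples are poses; labels and group ids are per molecule. Grouped
## stratified folds keep every pose of a molecule on one side of each
## split, which is what prevents pose-level leakage from inflating CV
## metrics. The positive class throughout is "agonist".

LIGAND_CLASSES <- c("antagonist", "agonist")  # factor levels; agonist = 1

as_label_factor <- function(labels) {
  if (is.numeric(labels)) labels <- LIGAND_CLASSES[labels + 1]
  factor(as.character(labels), levels = LIGAND_CLASSES)
}

#' Grouped stratified fold assignment
#'
#' Assigns whole groups (molecules) to folds so that no group is split and
#' per-fold label proportions stay as close to the global proportion as the
#' group sizes allow (greedy balanced assignment, largest groups first).
#'
#' @param labels per-sample labels (`"agonist"`/`"antagonist"`, or 0/1 with
#'   1 = agonist).
#' @param groups per-sample group (molecule) ids.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffle that breaks size ties.
#' @return integer vector of fold ids (1..k) per sample.
#' @export
grouped_stratified_folds <- function(labels, groups, k = 5L, seed = 1L) {
  stopifnot(length(labels) == length(groups))
  y <- as_label_factor(labels)
  if (any(is.na(y))) stop_fmt("labels must be agonist/antagonist (or 0/1)")
  groups <- as.character(groups)
  if (!all(nzchar(groups))) stop_fmt("group ids must be non-empty")
  gids <- unique(groups)
  if (length(gids) < k)
    stop_fmt("fewer groups (%d) than folds (%d)", length(gids), k)
  gsize <- table(groups)[gids]
  gpos <- tapply(y == "agonist", groups, sum)[gids]
  set.seed(seed)
  ord <- order(-as.numeric(gsize), runif(length(gids)))
  fold_pos <- numeric(k); fold_neg <- numeric(k)
  gfold <- setNames(integer(length(gids)), gids)
  pos_target <- sum(y == "agonist") / k
  neg_target <- sum(y == "antagonist") / k
  for (g in gids[ord]) {
    np <- gpos[[g]]; nn <- gsize[[g]] - np
    # increase in squared deviation from the per-fold label-count targets
    cost <- (fold_pos + np - pos_target)^2 - (fold_pos - pos_target)^2 +
            (fold_neg + nn - neg_target)^2 - (fold_neg - neg_target)^2
    best <- which.min(cost)
    gfold[g] <- best
    fold_pos[best] <- fold_pos[best] + np
    fold_neg[best] <- fold_neg[best] + nn
  }
  unname(gfold[groups])
}

#' Train a random-forest ligand-type classifier
#'
#' Default hyperparameters, no tuning; forest size defaults to 500 trees.
#' The classifier probability is the fraction of trees voting "antagonist"
#' (or "agonist"), which is what the downstream probability filter
#' consumes.
#'
#' @param x numeric feature matrix (poses x features).
#' @param labels per-row labels (see [grouped_stratified_folds()]).
#' @param trees number of trees (default 500).
#' @param seed RNG seed; the forest is deterministic given the seed.
#' @param groups optional per-row molecule ids stored for aggregation.
#' @return object of class `rf_ligand_classifier`.
#' @export
train_rf <- function(x, labels, trees = 500L, seed = 1L, groups = NULL) {
  x <- as.matrix(x)
  y <- as_label_factor(labels)
  if (any(is.na(y))) stop_fmt("labels must be agonist/antagonist (or 0/1)")
  tab <- table(y)
  if (any(tab < 2))
    stop_fmt("need at least 2 samples per class (got %s)",
             paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = trees, keep.inbag = TRUE,
                                   keep.forest = TRUE)
  structure(list(forest = rf, feature_names = colnames(x), trees = trees,
                 seed = seed, classes = LIGAND_CLASSES,
                 training = list(x = x, y = y, groups = groups)),
            class = "rf_ligand_classifier")
}

#' @export
print.rf_ligand_classifier <- function(x, ...) {
  cat(sprintf("<rf_ligand_classifier> %d trees, %d features, %d training samples\n",
              x$trees, length(x$feature_names), nrow(x$training$x)))
  invisible(x)
}

#' Predict class probabilities for pose feature rows
#'
#' @param object an `rf_ligand_classifier`.
#' @param newdata feature matrix with the model's feature columns.
#' @param class which class probability to return (default `"antagonist"`,
#'   the screening target).
#' @param ... unused.
#' @return numeric vector of per-row probabilities (fraction of trees
#'   voting for `class`).
#' @export
predict.rf_ligand_classifier <- function(object, newdata,
                                         class = "antagonist", ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop_fmt("feature length mismatch: model has %d, data has %d",
             length(object$feature_names), ncol(newdata))
  colnames(newdata) <- object$feature_names
  p <- predict(object$forest, newdata, type = "prob")
  as.numeric(p[, class])
}

#' Classification metrics from predictions
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean of the
#' two, accuracy = (TP+TN)/n; ROC AUC by trapezoidal integration of the
#' ROC curve over score thresholds. The positive class is "agonist".
#' Zero-denominator metrics are reported as 0 with a warning.
#'
#' @param scores predicted positive-class (agonist) scores in `[0, 1]`.
#' @param labels true labels.
#' @param threshold score cutoff for the class decision (default 0.5).
#' @return one-row data.frame: precision, recall, f1, accuracy, auc.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  y <- as_label_factor(labels) == "agonist"
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  safe_div <- function(num, den, what) {
    if (den == 0) { warn_fmt("%s undefined (zero denominator); reported as 0", what); 0 }
    else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warn_fmt("F1 undefined (precision + recall = 0); reported as 0"); 0
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(y)
  if (!any(y) || all(y)) stop_fmt("ROC AUC undefined: labels contain a single class")
  data.frame(precision = precision, recall = recall, f1 = f1,
             accuracy = accuracy, auc = roc_auc(scores, y))
}

#' Area under the ROC curve by trapezoidal integration
#'
#' @param scores positive-class scores.
#' @param positives logical (or label) vector of true positives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives) {
  if (!is.logical(positives)) positives <- as_label_factor(positives) == "agonist"
  ord <- order(scores, decreasing = TRUE)
  y <- positives[ord]; s <- scores[ord]
  np <- sum(y); nn <- sum(!y)
  tps <- cumsum(y); fps <- cumsum(!y)
  # collapse threshold ties to the last sample of each tied block
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, tps[keep] / np)
  fpr <- c(0, fps[keep] / nn)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Grouped stratified k-fold cross-validation of the forest
#'
#' @inheritParams train_rf
#' @param groups per-row molecule ids (folds are grouped by these).
#' @param k number of folds.
#' @return list of class `cv_report`: `per_fold` (metrics per fold),
#'   `mean` (column means), `folds` (per-row assignment). The absence of
#'   train/test group overlap is asserted for every fold.
#' @export
cross_validate <- function(x, labels, groups, k = 5L, trees = 500L, seed = 1L) {
  x <- as.matrix(x)
  y <- as_label_factor(labels)
  folds <- grouped_stratified_folds(y, groups, k = k, seed = seed)
  per_fold <- NULL
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(intersect(unique(groups[test]), unique(groups[!test]))))
      stop_fmt("group leakage detected in fold %d", f)  # cannot happen by construction
    model <- train_rf(x[!test, , drop = FALSE], y[!test], trees = trees,
                      seed = seed + f)
    sc <- predict(model, x[test, , drop = FALSE], class = "agonist")
    m <- evaluate(sc, y[test])
    per_fold <- rbind(per_fold, cbind(fold = f, m))
  }
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1, drop = FALSE]),
                 folds = folds, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold grouped CV\n", x$k))
  print(round(x$per_fold, 3), row.names = FALSE)
  cat("mean:", paste(sprintf("%s=%.3f", names(x$mean), x$mean), collapse = " "), "\n")
  invisible(x)
}

#' Molecule-level antagonist probability
#'
#' The per-molecule probability is the arithmetic mean of the per-pose
#' probabilities over all available poses of the molecule.
#'
#' @param model an `rf_ligand_classifier`.
#' @param pose_features feature matrix of the molecule's poses (>= 1 row).
#' @param class class whose probability is aggregated.
#' @return single probability in `[0, 1]`.
#' @export
predict_molecule_probability <- function(model, pose_features,
                                         class = "antagonist") {
  pose_features <- as.matrix(pose_features)
  if (!nrow(pose_features)) stop_fmt("molecule has no poses")
  mean(predict(model, pose_features, class = class))
}

#' Probability filter
#'
#' Retains candidates whose probability is at or above the threshold
#' (boundary inclusive: molecules strictly below the cutoff are neglected).
#'
#' @param candidates data.frame with a `probability` column, or a numeric
#'   vector of probabilities.
#' @param threshold retention cutoff (default 0.84).
#' @return the retained rows (or values), input order preserved.
#' @export
filter_by_probability <- function(candidates, threshold = 0.84) {
  p <- if (is.data.frame(candidates)) candidates$probability else candidates
  if (any(p < 0 | p > 1)) stop_fmt("probabilities must lie in [0, 1]")
  keep <- p >= threshold
  if (is.data.frame(candidates)) candidates[keep, , drop = FALSE] else candidates[keep]
}
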