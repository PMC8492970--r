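# Multiclass linear SVM (libsvm via e1071, one-vs-one) distinguishing
# NC/VMCI/MCI from homotopic-connectivity ROI voxel features plus clinical
# covariates, with a three-pairwise-t filter feature-selection rule, unit-
# variance scaling by training statistics, log2 C-grid tuning by stratified
# cross-validation, and an externally validated classification report.

# Vectorized pooled (equal-variance) two-sample t-test p-values per column.
pooled_t_pvalues <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2, ma)^2)
  vb <- colSums(sweep(xb, 2, mb)^2)
  df <- na + nb - 2
  sp2 <- (va + vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tval <- (ma - mb) / ifelse(se > 0, se, 1)
  p <- 2 * stats::pt(-abs(tval), df)
  p[se == 0] <- ifelse(abs(ma - mb)[se == 0] > 0, 0, 1)
  p
}

#' Filter feature selection by three pairwise t-tests
#'
#' For each feature, pooled two-sample t-tests are run between every pair of
#' the three classes; the feature is kept only if all three p-values are below
#' `alpha`. Deterministic given the data.
#'
#' @param x subjects x features matrix (training rows only, to avoid leakage).
#' @param y class labels (exactly 3 classes, each with n >= 2).
#' @param alpha per-test threshold (default 0.05).
#' @return logical keep-mask over the feature columns.
#' @export
select_features <- function(x, y, alpha = 0.05) {
  y <- factor(y)
  if (nlevels(y) != 3L) stop("feature optimization expects exactly 3 classes")
  if (any(table(y) < 2L)) stop("every class needs n >= 2")
  keep <- rep(TRUE, ncol(x))
  lv <- levels(y)
  for (pc in utils::combn(3L, 2L, simplify = FALSE)) {
    p <- pooled_t_pvalues(x[y == lv[pc[1]], , drop = FALSE],
                          x[y == lv[pc[2]], , drop = FALSE])
    keep <- keep & (p < alpha)
  }
  keep
}

#' Scale features to unit variance using training statistics
#'
#' Centers and scales every feature by the training-set mean and sd; validation
#' rows are transformed with the *training* statistics (never their own).
#' Zero-variance features are dropped with a warning.
#'
#' @param x_train training subjects x features matrix.
#' @param x_val optional validation matrix with the same columns.
#' @return list with scaled `train` and `val`, the `center` and `scale`
#'   vectors, and the logical `kept` column mask.
#' @export
scale_unit_variance <- function(x_train, x_val = NULL) {
  center <- colMeans(x_train)
  sds <- apply(x_train, 2, stats::sd)
  kept <- sds > 0
  if (!all(kept))
    warning(sum(!kept), " zero-variance feature(s) dropped before scaling")
  if (!any(kept)) stop("no features left after dropping zero-variance columns")
  tr <- scale(x_train[, kept, drop = FALSE], center = center[kept],
              scale = sds[kept])
  vl <- if (is.null(x_val)) NULL else
    scale(x_val[, kept, drop = FALSE], center = center[kept], scale = sds[kept])
  list(train = tr[, , drop = FALSE], val = vl, center = center[kept],
       scale = sds[kept], kept = kept)
}

#' Tune the linear-SVM cost parameter on a log2 grid
#'
#' Evaluates `C = 2^e` for every exponent in `exponents` (default -8 to 3 in
#' steps of 0.25, i.e. cmin, cmax, cstep = 2^-8, 2^3, 2^-2 read as a libsvm
#' grid of 45 candidates) by stratified k-fold cross-validated accuracy and
#' returns the best C; ties go to the smallest C. Fold assignment is
#' deterministic given `seed`.
#'
#' @param x scaled subjects x features matrix.
#' @param y class labels (>= 2 per class).
#' @param exponents log2 exponent grid.
#' @param n_folds folds for stratified CV (reduced automatically if a class is
#'   smaller).
#' @param seed integer seed for the fold shuffle.
#' @return list with `C`, `exponent`, and the per-candidate `accuracy` vector.
#' @export
tune_c <- function(x, y, exponents = seq(-8, 3, by = 0.25), n_folds = 5L,
                   seed = 1L) {
  if (length(exponents) == 0L) stop("empty C grid")
  y <- factor(y)
  if (any(table(y) < 2L)) stop("every class needs n >= 2")
  n_folds <- min(n_folds, min(table(y)))
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  acc <- vapply(exponents, function(e) {
    C <- 2^e
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = C, scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which(acc == max(acc))[1]   # grid is ascending: first max = smallest C
  list(C = 2^exponents[best], exponent = exponents[best],
       accuracy = stats::setNames(acc, sprintf("2^%g", exponents)))
}

#' Train a multiclass linear SVM once and predict validation labels
#'
#' One-vs-one multiclass linear-kernel SVM (libsvm's internal scheme), trained
#' on the training rows only and applied unchanged to the validation rows.
#'
#' @param x_train,y_train scaled training features and labels.
#' @param x_val validation features scaled with training statistics.
#' @param cost the C parameter (e.g. from [tune_c()]).
#' @return factor of predicted validation labels; the fitted model is attached
#'   as attribute `model`.
#' @export
train_predict <- function(x_train, y_train, x_val, cost = 1) {
  y_train <- factor(y_train)
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- stats::predict(fit, x_val)
  attr(pred, "model") <- fit
  pred
}

#' Classification report: confusion matrix and per-class metrics
#'
#' Confusion matrix (true x predicted), per-class precision
#' (`TP / predicted`), recall (`TP / true`) and F1 (harmonic mean), overall
#' accuracy (`trace / total`) and the chance baseline `1 / n_classes`. A class
#' that is never predicted gets precision 0 and is flagged.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes optional class ordering (default: union of levels).
#' @return object of class `class_report`: `confusion`, `precision`, `recall`,
#'   `f1`, `accuracy`, `baseline_accuracy`, `never_predicted`.
#' @export
class_report <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.null(classes)) classes <- union(levels(factor(y_true)), levels(factor(y_pred)))
  y_true <- factor(y_true, levels = classes)
  y_pred <- factor(y_pred, levels = classes)
  cm <- table(true = y_true, predicted = y_pred)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  never <- pred_n == 0
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = cm,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = sum(tp) / sum(cm),
                 baseline_accuracy = 1 / length(classes),
                 never_predicted = names(pred_n)[never]),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  tab <- data.frame(precision = sprintf("%.2f%%", 100 * x$precision),
                    recall = sprintf("%.2f%%", 100 * x$recall),
                    f1 = sprintf("%.2f%%", 100 * x$f1))
  rownames(tab) <- rownames(x$confusion)
  print(tab)
  cat(sprintf("Accuracy %.2f%% (baseline %.2f%%)\n",
              100 * x$accuracy, 100 * x$baseline_accuracy))
  if (length(x$never_predicted))
    cat("Never predicted:", paste(x$never_predicted, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the ROI + covariate feature matrix
#'
#' Features are the Fisher-z homotopic-connectivity values at every ROI voxel
#' plus age, sex (coded M = 1, F = 0), education and MMSE, in a fixed recorded
#' order.
#'
#' @param maps named list of per-subject [vmhc_subject()] maps (or 3D arrays),
#'   in the same order as `subjects`.
#' @param roi_voxels integer vector of linear voxel indices (e.g. pooled from a
#'   `cluster_table`'s voxel lists).
#' @param subjects data.frame with columns age, sex, education, mmse.
#' @return numeric subjects x (voxels + 4) matrix with column names.
#' @export
feature_matrix <- function(maps, roi_voxels, subjects) {
  vox <- do.call(rbind, lapply(maps, function(m) {
    v <- if (inherits(m, "vmhc_map")) m$z else m
    as.vector(v)[roi_voxels]
  }))
  colnames(vox) <- paste0("z_vox", roi_voxels)
  cov <- cbind(age = subjects$age,
               sex = as.numeric(subjects$sex == "M"),
               education = subjects$education,
               mmse = subjects$mmse)
  cbind(vox, cov)
}

#' End-to-end classifier: selection, scaling, tuning, training, validation
#'
#' Runs the full classification protocol: t-test filter feature selection on
#' the training rows, unit-variance scaling by training statistics, C tuning
#' on the log2 grid by stratified CV, a single multiclass linear SVM fit, and
#' external-validation reporting. Set `select_on = "all"` to reproduce the
#' laxer variant where the filter sees validation rows too.
#'
#' @param x_train,y_train training features/labels.
#' @param x_val,y_val validation features/labels.
#' @param alpha filter threshold (default 0.05).
#' @param exponents C-grid exponents.
#' @param n_folds CV folds for tuning.
#' @param seed RNG seed for fold assignment.
#' @param select_on "train" (default) or "all".
#' @return list with `report` ([class_report()]), `C`, `kept` feature mask,
#'   `n_features`, `predicted`, and the scaling record.
#' @export
hfc_classifier <- function(x_train, y_train, x_val, y_val, alpha = 0.05,
                           exponents = seq(-8, 3, by = 0.25), n_folds = 5L,
                           seed = 1L, select_on = c("train", "all")) {
  select_on <- match.arg(select_on)
  keep <- if (select_on == "train") select_features(x_train, y_train, alpha)
          else select_features(rbind(x_train, x_val), c(y_train, y_val), alpha)
  if (!any(keep)) stop("feature optimization removed every feature")
  sc <- scale_unit_variance(x_train[, keep, drop = FALSE],
                            x_val[, keep, drop = FALSE])
  tuned <- tune_c(sc$train, y_train, exponents, n_folds, seed)
  pred <- train_predict(sc$train, y_train, sc$val, tuned$C)
  list(report = class_report(y_val, pred, classes = levels(factor(y_train))),
       C = tuned$C, cv_accuracy = tuned$accuracy, kept = keep,
       n_features = sum(keep), predicted = pred,
       scaling = list(center = sc$center, scale = sc$scale))
}
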