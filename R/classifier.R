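#' Configuration of the classification pipeline
#'
#' Defaults reproduce the motivating study's settings: 50 features
#' selected per fold by two-sample t-tests (all selected p-values were
#' below 0.001 there, so \code{p_ceiling} warns when exceeded), LLE with
#' k = 23 neighbors and d = 15 dimensions, and a Gaussian-RBF SVM with
#' sigma = 3. The soft-margin cost was not reported; the default is 1.
#'
#' @param n_features number of edges selected per fold.
#' @param p_ceiling warn when a selected feature's p-value exceeds this
#'   (warn-only; NULL disables).
#' @param k_lle,d_lle LLE neighbor count and embedding dimension.
#' @param sigma RBF kernel width.
#' @param cost SVM soft-margin cost.
#' @param use_lle embed before the SVM (FALSE gives the plain TSTT + SVM
#'   comparison arm).
#' @param standardize z-score selected features with training-fold
#'   statistics before LLE/SVM.
#' @param var_equal Student (TRUE) or Welch selection tests.
#' @param gamma_form kernel dialect, see \code{\link{train_svm}}.
#' @param lle_reg LLE local-Gram ridge factor.
#' @param seed optional seed recorded with results.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_features = 50, p_ceiling = 0.001,
                            k_lle = 23, d_lle = 15, sigma = 3, cost = 1,
                            use_lle = TRUE, standardize = TRUE,
                            var_equal = TRUE, gamma_form = "2sigma2",
                            lle_reg = 1e-3, seed = NULL) {
  stopifnot(n_features >= 1, sigma > 0, cost > 0, k_lle >= 1, d_lle >= 1)
  structure(list(n_features = as.integer(n_features), p_ceiling = p_ceiling,
                 k_lle = as.integer(k_lle), d_lle = as.integer(d_lle),
                 sigma = sigma, cost = cost, use_lle = isTRUE(use_lle),
                 standardize = isTRUE(standardize),
                 var_equal = isTRUE(var_equal),
                 gamma_form = match.arg(gamma_form, c("2sigma2", "sigma2")),
                 lle_reg = lle_reg, seed = seed),
            class = "pipeline_config")
}

#' Select the most discriminating features by two-sample t-tests
#'
#' Ranks features by ascending p-value (ties broken by larger |t|, then by
#' smaller index) and returns the best \code{n_features}. Features with
#' zero variance in both groups get p = 1.
#'
#' @param x training feature matrix (subjects x features).
#' @param y training labels (two classes).
#' @param n_features number of features to keep.
#' @param p_ceiling warn if any selected p-value exceeds this (NULL: no
#'   check).
#' @param var_equal Student (TRUE) or Welch tests.
#' @return list with \code{indices} (sorted ascending), \code{p_values}
#'   and \code{t_values} aligned with \code{indices}.
#' @export
select_features <- function(x, y, n_features, p_ceiling = NULL,
                            var_equal = TRUE) {
  if (n_features > ncol(x))
    stop("n_features (", n_features, ") exceeds the number of features (",
         ncol(x), ")")
  tt <- col_ttest(x, y, var_equal)
  ord <- order(tt$p, -abs(tt$t), seq_along(tt$p))[seq_len(n_features)]
  sel <- sort(ord)
  if (!is.null(p_ceiling) && any(tt$p[sel] > p_ceiling))
    warning(sum(tt$p[sel] > p_ceiling), " selected feature(s) have p > ",
            p_ceiling)
  list(indices = sel, p_values = tt$p[sel], t_values = tt$t[sel])
}

# z-scoring with training-fold statistics; zero-sd features pass through.
.fold_scaler <- function(x_train) {
  mu <- colMeans(x_train)
  s <- apply(x_train, 2, stats::sd)
  s[s == 0] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Classification metrics from a confusion table
#'
#' Sensitivity SS = TP/(TP+FN), specificity SC = TN/(TN+FP) and
#' generalization rate GR = (TP+TN)/(TP+TN+FP+FN), as percentages. TP/TN
#' are patients/controls predicted accurately; FP controls classified as
#' patients; FN patients classified as controls.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return list with \code{ss}, \code{sc}, \code{gr} (percent, full
#'   precision; round only for reporting).
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  list(ss = 100 * tp / (tp + fn),
       sc = 100 * tn / (tn + fp),
       gr = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' Nested leave-one-out cross-validation of the full pipeline
#'
#' For each fold the left-out subject is removed; feature selection,
#' standardization statistics, the LLE embedding and the SVM are all
#' computed from the remaining subjects only, and the left-out subject is
#' projected through the out-of-sample LLE extension and scored. No
#' information from the test subject reaches any training-side step.
#'
#' @param cohort a \code{conn_cohort}.
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{cv_result}: per-fold results (left-out
#'   id, selected edges, p-values, prediction, signed score), confusion
#'   counts, SS/SC/GR percentages, per-subject scores, ROC points and AUC.
#' @export
run_loocv <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "conn_cohort"))
  x <- cohort$features
  y <- cohort$labels
  n <- nrow(x)
  if (n < 4) stop("LOOCV needs at least 4 subjects")
  if (config$n_features > ncol(x))
    stop("n_features (", config$n_features,
         ") exceeds the feature length (", ncol(x), ")")
  folds <- vector("list", n)
  scores <- numeric(n)
  preds <- character(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < 2)
      stop("fold ", i, ": training set lost a class")
    xtr <- x[-i, , drop = FALSE]
    sel <- select_features(xtr, ytr, config$n_features, config$p_ceiling,
                           config$var_equal)
    ztr <- xtr[, sel$indices, drop = FALSE]
    zte <- x[i, sel$indices, drop = FALSE]
    if (config$standardize) {
      scale_fn <- .fold_scaler(ztr)
      ztr <- scale_fn(ztr); zte <- scale_fn(zte)
    }
    if (config$use_lle) {
      lle <- fit_lle(ztr, config$k_lle, config$d_lle, config$lle_reg)
      ztr <- lle$y
      zte <- transform_lle(lle, zte)
    }
    svm <- train_svm(ztr, ytr, config$sigma, config$cost, config$gamma_form)
    dec <- svm_decision(svm, zte)
    scores[i] <- dec$score
    preds[i] <- as.character(dec$prediction)
    folds[[i]] <- list(left_out = cohort$subject_ids[i],
                       selected = sel$indices, p_values = sel$p_values,
                       prediction = preds[i], score = scores[i])
  }
  truth <- as.character(y)
  tp <- sum(preds == "patient" & truth == "patient")
  tn <- sum(preds == "control" & truth == "control")
  fp <- sum(preds == "patient" & truth == "control")
  fn <- sum(preds == "control" & truth == "patient")
  metrics <- classification_metrics(tp, tn, fp, fn)
  roc <- roc_curve(scores, truth)
  structure(list(folds = folds, tp = tp, tn = tn, fp = fp, fn = fn,
                 ss = metrics$ss, sc = metrics$sc, gr = metrics$gr,
                 scores = scores, predictions = preds, labels = truth,
                 subject_ids = cohort$subject_ids,
                 roc = roc$points, auc = roc$auc, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV over %d subjects: GR = %.1f%%, SS = %.1f%%, SC = %.1f%%, AUC = %.4f\n",
    length(x$scores), x$gr, x$ss, x$sc, x$auc))
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' Each observed score serves as a threshold (predict patient when score
#' >= threshold); tied scores cross the threshold together. The AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordance probability
#' with ties counted 1/2.
#'
#' @param scores signed decision scores (higher = more patient-like).
#' @param labels control/patient labels.
#' @return list with \code{points} (data.frame: threshold, sensitivity,
#'   specificity, fpr) and \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("control", "patient"))
  if (anyNA(labels)) stop("labels must be 'control' or 'patient'")
  np <- sum(labels == "patient"); nc <- sum(labels == "control")
  if (np == 0 || nc == 0) stop("both classes are required for a ROC curve")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) sum(scores >= t & labels == "patient") / np,
                 numeric(1))
  spec <- vapply(th, function(t) sum(scores < t & labels == "control") / nc,
                 numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + sens[-1]) / 2)
  list(points = data.frame(threshold = th, sensitivity = sens,
                           specificity = spec, fpr = fpr),
       auc = auc)
}
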