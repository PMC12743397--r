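#' Train a linear soft-margin SVM separating a subpopulation from healthy
#' controls
#'
#' Fits a linear support vector machine (via libsvm) with regularization
#' parameter `C = box_constraint` on features divided by `kernel_scale`,
#' without internal rescaling. The returned weights are expressed on the
#' original feature scale, so the decision function is
#' `f(x) = x %*% weights + bias`, with the sign convention that positive
#' decision values lie on the healthy-control side of the hyperplane
#' (larger is healthier).
#'
#' @param pathologic_scores Matrix `[n1 x P]` of subpopulation PC scores.
#' @param hc_scores Matrix `[n2 x P]` of healthy-control PC scores.
#' @param box_constraint Soft-margin cost C (default 1).
#' @param kernel_scale Feature divisor (default 1); scaling all features by
#'   c and `kernel_scale` by c leaves decision values unchanged.
#' @return Object of class `linear_gait_classifier`: `weights`, `bias`,
#'   `orientation = "positive_is_hc"`, `background_mean` (training feature
#'   mean, used as the Shapley background), plus the training settings.
#' @export
train_linear_svm <- function(pathologic_scores, hc_scores,
                             box_constraint = 1, kernel_scale = 1) {
  pathologic_scores <- as.matrix(pathologic_scores)
  hc_scores <- as.matrix(hc_scores)
  n1 <- nrow(pathologic_scores)
  n2 <- nrow(hc_scores)
  if (n1 < 1 || n2 < 1) {
    stop("both classes need at least one subject", call. = FALSE)
  }
  if (ncol(pathologic_scores) != ncol(hc_scores)) {
    stop("feature dimension mismatch between classes", call. = FALSE)
  }
  stopifnot(box_constraint > 0, kernel_scale > 0)
  x <- rbind(pathologic_scores, hc_scores) / kernel_scale
  y <- factor(c(rep("pathologic", n1), rep("HC", n2)),
              levels = c("pathologic", "HC"))
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = box_constraint,
                    scale = FALSE, tolerance = 1e-7)
  w_scaled <- drop(t(fit$coefs) %*% fit$SV)
  bias <- -fit$rho
  weights <- w_scaled / kernel_scale
  if (sqrt(sum(weights^2)) == 0) {
    stop("degenerate SVM solution: zero weight vector", call. = FALSE)
  }
  # orientation: positive decision value must mean HC side
  dv <- drop(x %*% w_scaled) + bias
  pred <- stats::predict(fit, x)
  i <- which.max(abs(dv))
  positive_is_pathologic <- (dv[i] > 0) == (pred[i] == "pathologic")
  if (positive_is_pathologic) {
    weights <- -weights
    bias <- -bias
  }
  structure(list(weights = weights, bias = bias,
                 orientation = "positive_is_hc",
                 box_constraint = box_constraint,
                 kernel_scale = kernel_scale,
                 background_mean = colMeans(rbind(pathologic_scores,
                                                  hc_scores)),
                 n_pathologic = n1, n_hc = n2),
            class = "linear_gait_classifier")
}

#' Decision values of a linear gait classifier
#'
#' @param classifier A [train_linear_svm()] result.
#' @param scores Matrix `[m x P]` or a single score vector.
#' @return Numeric vector of signed decision values (positive = HC side).
#' @export
decision_values <- function(classifier, scores) {
  stopifnot(inherits(classifier, "linear_gait_classifier"))
  scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else
    as.matrix(scores)
  if (ncol(scores) != length(classifier$weights)) {
    stop("score dimension (", ncol(scores),
         ") does not match the classifier (",
         length(classifier$weights), ")", call. = FALSE)
  }
  drop(scores %*% classifier$weights) + classifier$bias
}

#' Pathologic ratio
#'
#' Percentage of a subpopulation's members classified to the pathological
#' side of the hyperplane, reported to one decimal.
#'
#' @param n_pathologic_classified Count classified as pathologic.
#' @param n_total Subpopulation size (> 0).
#' @return Percentage rounded to one decimal.
#' @examples
#' pathologic_ratio(23, 27) # 85.2
#' @export
pathologic_ratio <- function(n_pathologic_classified, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_pathologic_classified < 0 || n_pathologic_classified > n_total) {
    stop("need 0 <= n_pathologic_classified <= n_total", call. = FALSE)
  }
  round(100 * n_pathologic_classified / n_total, 1)
}

rank_auc <- function(dv_pathologic, dv_hc) {
  # AUC as the rank statistic P(dv_HC > dv_pathologic), ties counting half
  r <- pROC::roc(response = c(rep("pathologic", length(dv_pathologic)),
                              rep("HC", length(dv_hc))),
                 predictor = c(dv_pathologic, dv_hc),
                 levels = c("pathologic", "HC"), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

classification_report <- function(subpop_id, era, dv_pathologic, dv_hc) {
  pred_path <- dv_pathologic < 0
  pred_hc <- dv_hc >= 0
  n1 <- length(dv_pathologic)
  n2 <- length(dv_hc)
  data.frame(
    subpop = subpop_id,
    era = era,
    classification_rate = round(100 * (sum(pred_path) + sum(pred_hc)) /
                                  (n1 + n2), 1),
    n_classified_pathologic = sum(pred_path),
    n_classified_hc = n1 - sum(pred_path),
    pathologic_ratio = pathologic_ratio(sum(pred_path), n1),
    sensitivity = sum(pred_path) / n1,
    specificity = sum(pred_hc) / n2,
    roc_auc = rank_auc(dv_pathologic, dv_hc),
    stringsAsFactors = FALSE)
}

#' Cross-validated classification report for a subpopulation-vs-HC SVM
#'
#' Stratified 10-fold cross-validation (seeded): out-of-fold decision values
#' are pooled, subjects with negative decision values count as pathologic,
#' and the pooled predictions yield the classification rate, pathologic
#' ratio, sensitivity (pathologic = positive), specificity and rank-based
#' ROC-AUC. If either class has fewer members than folds, the fold count is
#' reduced with a warning.
#'
#' @inheritParams train_linear_svm
#' @param seed Integer seed for the fold split.
#' @param n_folds Number of folds (default 10).
#' @param subpop_id Label used in the report (default 1).
#' @return List of class `cv_report`: `report` (one-row data frame),
#'   `cv_decision_values`, `cv_labels`, `fold` and `final_model` (the
#'   classifier trained on all data).
#' @export
crossvalidate_10fold <- function(pathologic_scores, hc_scores, seed = 1L,
                                 n_folds = 10L, box_constraint = 1,
                                 kernel_scale = 1, subpop_id = 1L) {
  pathologic_scores <- as.matrix(pathologic_scores)
  hc_scores <- as.matrix(hc_scores)
  n1 <- nrow(pathologic_scores)
  n2 <- nrow(hc_scores)
  if (n1 + n2 < 10) stop("need at least 10 subjects for cross-validation",
                         call. = FALSE)
  k <- min(n_folds, n1, n2)
  if (k < n_folds) {
    warning("reducing folds from ", n_folds, " to ", k,
            " (smallest class has ", min(n1, n2), " members)", call. = FALSE)
  }
  set.seed(seed)
  fold <- c(sample(rep_len(seq_len(k), n1)), sample(rep_len(seq_len(k), n2)))
  x <- rbind(pathologic_scores, hc_scores)
  is_path <- c(rep(TRUE, n1), rep(FALSE, n2))
  dv <- numeric(n1 + n2)
  for (f in seq_len(k)) {
    test <- fold == f
    m <- train_linear_svm(x[!test & is_path, , drop = FALSE],
                          x[!test & !is_path, , drop = FALSE],
                          box_constraint, kernel_scale)
    dv[test] <- decision_values(m, x[test, , drop = FALSE])
  }
  final <- train_linear_svm(pathologic_scores, hc_scores, box_constraint,
                            kernel_scale)
  structure(list(report = classification_report(subpop_id, "pre",
                                                dv[is_path], dv[!is_path]),
                 cv_decision_values = dv,
                 cv_labels = ifelse(is_path, "pathologic", "HC"),
                 fold = fold,
                 final_model = final),
            class = "cv_report")
}

#' Project the paired post-surgery cohort through a trained classifier
#'
#' Applies the final (all-data) model's decision function to the follow-up
#' scores; subjects with negative (pathologic-side) decision values count as
#' pathologic. Sensitivity is the proportion of follow-up subjects
#' classified pathologic; specificity and ROC-AUC are computed against the
#' healthy-control cohort under the same final model.
#'
#' @param classifier A `linear_gait_classifier` (the final model).
#' @param followup_scores Matrix `[m x P]` of post-surgery PC scores.
#' @param hc_scores Matrix `[n2 x P]` of healthy-control scores.
#' @param subpop_id Label used in the report.
#' @return One-row data frame shaped like the cross-validation report, with
#'   `era = "post"`.
#' @export
project_followup <- function(classifier, followup_scores, hc_scores,
                             subpop_id = 1L) {
  if (is.null(dim(followup_scores))) {
    followup_scores <- matrix(followup_scores, nrow = 1)
  }
  if (nrow(followup_scores) < 1) {
    stop("need at least one follow-up subject", call. = FALSE)
  }
  dv_f <- decision_values(classifier, followup_scores)
  dv_hc <- decision_values(classifier, hc_scores)
  rep <- classification_report(subpop_id, "post", dv_f, dv_hc)
  rep$classification_rate <- NA_real_  # undefined: no held-out predictions
  rep
}
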