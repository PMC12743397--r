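#' Closed-form Shapley values for a linear decision function
#'
#' For a linear model with an independent-features background, the Shapley
#' value of feature i is `phi_i = w_i * (x_i - background_i)` and the
#' expected value is the decision function at the background point. The
#' efficiency identity `sum(phi) = f(x) - f(background)` holds exactly.
#' The background is the feature mean of the classifier's training set
#' (subpopulation plus healthy controls).
#'
#' @param weights,bias Linear decision function `f(x) = w . x + b`.
#' @param score_vector Feature vector of the explained subject.
#' @param background_mean Background feature vector.
#' @return List of class `shapley_vector`: `phi`, `expected_value`,
#'   `decision`.
#' @export
linear_shap <- function(weights, bias, score_vector, background_mean) {
  if (length(weights) != length(score_vector) ||
      length(weights) != length(background_mean)) {
    stop("weights, score_vector and background_mean must have equal length",
         call. = FALSE)
  }
  phi <- weights * (score_vector - background_mean)
  structure(list(phi = phi,
                 expected_value = sum(weights * background_mean) + bias,
                 decision = sum(weights * score_vector) + bias),
            class = "shapley_vector")
}

#' Back-project Shapley-weighted PC scores to per-waveform importance
#'
#' For each subject, each principal component's absolute Shapley value is
#' multiplied by the corresponding PC score; the weighted score vector is
#' multiplied by the eigenvector matrix to reconstruct a waveform-space
#' pattern, which is reshaped to the channel-by-timepoint grid. A channel's
#' contribution for one subject is the mean absolute reconstructed value
#' over the stance grid (absolute values prevent cancellation between
#' stance sub-phases), and its importance is the mean contribution over the
#' subpopulation's subjects. Channels are ranked by decreasing importance,
#' ties broken by channel-list order.
#'
#' @param classifier A `linear_gait_classifier`.
#' @param scores Matrix `[n x P]` of the subpopulation subjects' PC scores.
#' @param basis The [fit_pca()] `eigen_basis` (same P as the classifier).
#' @param channels Character vector of the channel names (defines the
#'   reshape and the tie-break order).
#' @param subpop_id Label carried into the profile (default 1).
#' @return Object of class `importance_profile`: `subpop`, `importance`
#'   (named numeric, channel order preserved), `ranking`, `top5`.
#' @export
waveform_importance <- function(classifier, scores, basis, channels,
                                subpop_id = 1L) {
  stopifnot(inherits(classifier, "linear_gait_classifier"),
            inherits(basis, "eigen_basis"))
  scores <- as.matrix(scores)
  if (nrow(scores) == 0) stop("empty subject set", call. = FALSE)
  p <- length(classifier$weights)
  if (ncol(scores) != p || ncol(basis$eigenvectors) != p) {
    stop("classifier, scores and basis must share the same number of ",
         "components", call. = FALSE)
  }
  nc <- length(channels)
  nt <- length(basis$center) / nc
  if (nt != round(nt)) {
    stop("basis dimension is not a multiple of the channel count",
         call. = FALSE)
  }
  contrib <- matrix(NA_real_, nrow(scores), nc)
  for (i in seq_len(nrow(scores))) {
    phi <- classifier$weights * (scores[i, ] - classifier$background_mean)
    u <- abs(phi) * scores[i, ]
    r <- drop(basis$eigenvectors %*% u)          # length D, channel-major
    rc <- matrix(r, nrow = nt)                   # [timepoint x channel]
    contrib[i, ] <- colMeans(abs(rc))
  }
  importance <- stats::setNames(colMeans(contrib), channels)
  ord <- order(-importance, seq_along(importance))
  ranking <- channels[ord]
  structure(list(subpop = subpop_id,
                 importance = importance,
                 ranking = ranking,
                 top5 = ranking[seq_len(min(5L, nc))]),
            class = "importance_profile")
}

#' Top-k most important channels
#'
#' @param profile An [waveform_importance()] result.
#' @param k Number of channels (default 5).
#' @return Character vector, the first k of the ranking.
#' @export
top_k <- function(profile, k = 5L) {
  stopifnot(inherits(profile, "importance_profile"))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > length(profile$ranking)) {
    stop("k exceeds the number of channels", call. = FALSE)
  }
  profile$ranking[seq_len(k)]
}

#' Classifier-oriented gait score (COGS)
#'
#' Signed orthogonal (minimal) distance of a subject's reduced feature
#' vector to the SVM hyperplane, `(w . x + b) / ||w||`, oriented so that
#' positive values lie on the healthy-control side: larger means closer to
#' healthy gait. Invariant to rescaling `(w, b)` by any positive constant.
#'
#' @param weights,bias Hyperplane parameters (or pass a
#'   `linear_gait_classifier` as `weights`).
#' @param score_vector Feature vector, or a matrix of one subject per row.
#' @return Signed distance(s) in standardized-feature units.
#' @examples
#' cogs(c(3, 4), 0, c(3, 4)) # 5
#' @export
cogs <- function(weights, bias = NULL, score_vector) {
  if (inherits(weights, "linear_gait_classifier")) {
    bias <- weights$bias
    weights <- weights$weights
  }
  nrm <- sqrt(sum(weights^2))
  if (nrm == 0) stop("zero weight vector", call. = FALSE)
  x <- if (is.null(dim(score_vector))) matrix(score_vector, nrow = 1) else
    as.matrix(score_vector)
  if (ncol(x) != length(weights)) {
    stop("dimension mismatch between weights and scores", call. = FALSE)
  }
  drop(x %*% weights + bias) / nrm
}
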