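#' Average waveforms over trials
#'
#' Arithmetic mean over the trial axis, yielding one mean waveform per
#' subject and channel; all subsequent analysis operates on these
#' trial-averaged curves.
#'
#' @param study A `waveform_study`.
#' @return Numeric array `[subject x channel x timepoint]` with dimnames.
#' @export
average_trials <- function(study) {
  stopifnot(inherits(study, "waveform_study"))
  d <- study$data
  bad <- which(apply(d, 1, function(x) any(!is.finite(x))))
  if (length(bad)) {
    stop("missing or non-finite trial data for subject(s): ",
         paste(study$subjects$subject_id[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- apply(d, c(1, 3, 4), mean)
  dimnames(out) <- dimnames(d)[c(1, 3, 4)]
  out
}

#' Healthy-control standardization statistics
#'
#' Pointwise mean and sample standard deviation (denominator n - 1) of the
#' healthy-control subject-mean waveforms; used to z-standardize every
#' cohort into the dimensional space of the healthy controls.
#'
#' @param hc_means Array `[subject x channel x timepoint]` of HC
#'   trial-averaged waveforms.
#' @return Object of class `standardization_stats` with `mean` and `sd`
#'   arrays `[channel x timepoint]` and `source_group = "HC"`.
#' @export
fit_standardization <- function(hc_means) {
  stopifnot(length(dim(hc_means)) == 3)
  n <- dim(hc_means)[1]
  if (n < 2) stop("need at least 2 HC subjects", call. = FALSE)
  mu <- apply(hc_means, c(2, 3), mean)
  sd_ <- apply(hc_means, c(2, 3), stats::sd)
  zero <- which(sd_ == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    ch <- dimnames(hc_means)[[2]]
    lab <- if (is.null(ch)) zero[1, 1] else ch[zero[1, 1]]
    stop("zero HC standard deviation at channel '", lab, "', timepoint ",
         zero[1, 2] - 1L, " (degenerate input)", call. = FALSE)
  }
  structure(list(mean = mu, sd = sd_, source_group = "HC"),
            class = "standardization_stats")
}

#' Standardize subject-mean waveforms by HC statistics
#'
#' Elementwise `(x - mean) / sd` with the healthy-control statistics, so all
#' cohorts are expressed in the same standardized space.
#'
#' @param subject_means Array `[subject x channel x timepoint]`.
#' @param stats A [fit_standardization()] result.
#' @return Array of the same shape.
#' @export
standardize_waveforms <- function(subject_means, stats) {
  stopifnot(inherits(stats, "standardization_stats"),
            length(dim(subject_means)) == 3)
  if (!all(dim(subject_means)[2:3] == dim(stats$mean))) {
    stop("shape mismatch between data (",
         paste(dim(subject_means)[2:3], collapse = " x "),
         ") and standardization statistics (",
         paste(dim(stats$mean), collapse = " x "), ")", call. = FALSE)
  }
  out <- sweep(subject_means, c(2, 3), stats$mean, `-`)
  sweep(out, c(2, 3), stats$sd, `/`)
}

#' Flatten standardized waveforms to a subject-by-variable matrix
#'
#' Channel-major concatenation: channel 1 timepoints first, then channel 2,
#' and so on; element (channel j, time t, both 0-based) lands at column
#' `j * n_timepoints + t + 1`. With the standard 18 x 101 grid this yields
#' 1818 variables. Invertible via [unflatten_waveforms()].
#'
#' @param x Array `[subject x channel x timepoint]`.
#' @return Matrix `[subject x (channel * timepoint)]`.
#' @export
flatten_waveforms <- function(x) {
  stopifnot(length(dim(x)) == 3)
  ns <- dim(x)[1]; nc <- dim(x)[2]; nt <- dim(x)[3]
  out <- matrix(aperm(x, c(3, 2, 1)), nrow = nc * nt, ncol = ns)
  out <- t(out)
  rownames(out) <- dimnames(x)[[1]]
  if (!is.null(dimnames(x)[[2]])) {
    colnames(out) <- paste(rep(dimnames(x)[[2]], each = nt),
                           sprintf("t%03d", seq_len(nt) - 1L), sep = "_")
  }
  out
}

#' @rdname flatten_waveforms
#' @param mat Matrix `[subject x D]`.
#' @param n_channels,n_timepoints Grid dimensions with
#'   `n_channels * n_timepoints == ncol(mat)`.
#' @param channels Optional channel names.
#' @export
unflatten_waveforms <- function(mat, n_channels, n_timepoints,
                                channels = NULL) {
  stopifnot(ncol(mat) == n_channels * n_timepoints)
  out <- aperm(array(t(mat), dim = c(n_timepoints, n_channels, nrow(mat))),
               c(3, 2, 1))
  dimnames(out) <- list(rownames(mat), channels, NULL)
  out
}

#' Fit a principal-component eigenbasis on the pathological cohort
#'
#' PCA of the flattened standardized HOA matrix: the basis center is the
#' column mean of the fitting cohort, eigenvectors are the top right
#' singular vectors of the centered matrix, and the number of retained
#' components is the smallest P whose cumulative explained-variance ratio
#' reaches `variance_threshold` (default 90%). Each eigenvector's sign is
#' fixed so its largest-magnitude element is positive, making the basis
#' reproducible across linear-algebra backends.
#'
#' @param mat Matrix `[N x D]`, N >= 2.
#' @param variance_threshold Cumulative explained-variance target in (0, 1].
#' @return Object of class `eigen_basis`: `center` (length D),
#'   `eigenvectors` (`D x P`, orthonormal columns), `explained_variance_ratio`
#'   (length P), `explained_variance_ratio_all`, `n_retained`,
#'   `variance_threshold`, and `scores` (`N x P`, the fitting cohort's own
#'   principal-component scores).
#' @export
fit_pca <- function(mat, variance_threshold = 0.90) {
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1 ||
      variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance_threshold must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  center <- colMeans(mat)
  xc <- sweep(mat, 2, center)
  sv <- svd(xc)
  ev <- sv$d^2
  ratio <- ev / sum(ev)
  cum <- cumsum(ratio)
  p <- which(cum >= variance_threshold - 1e-12)[1]
  if (is.na(p)) p <- length(ratio)
  vecs <- sv$v[, seq_len(p), drop = FALSE]
  scores <- sweep(sv$u[, seq_len(p), drop = FALSE], 2,
                  sv$d[seq_len(p)], `*`)
  # sign convention: largest-magnitude element of each eigenvector positive
  for (j in seq_len(p)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) {
      vecs[, j] <- -vecs[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(vecs) <- colnames(scores) <- sprintf("pc%d", seq_len(p))
  rownames(scores) <- rownames(mat)
  structure(list(center = center,
                 eigenvectors = vecs,
                 explained_variance_ratio = ratio[seq_len(p)],
                 explained_variance_ratio_all = ratio,
                 n_retained = p,
                 variance_threshold = variance_threshold,
                 scores = scores),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat("eigen_basis:", x$n_retained, "components over",
      nrow(x$eigenvectors), "variables;",
      sprintf("%.1f%%", 100 * sum(x$explained_variance_ratio)),
      "variance explained (threshold",
      sprintf("%.0f%%)\n", 100 * x$variance_threshold))
  invisible(x)
}

#' Project a cohort into a fitted eigenbasis
#'
#' Centers the flattened matrix with the fitting cohort's column means and
#' multiplies by the eigenvector matrix, expressing any cohort in the shared
#' reduced feature space. Projecting the fitting cohort itself reproduces
#' its own PC scores.
#'
#' @param mat Matrix `[M x D]`.
#' @param basis An [fit_pca()] result.
#' @param subject_ids,group Optional per-row annotations.
#' @return Object of class `reduced_feature_set`: `scores` (`M x P`),
#'   `subject_ids`, `group`.
#' @export
project_onto_basis <- function(mat, basis, subject_ids = rownames(mat),
                               group = NULL) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (ncol(mat) != length(basis$center)) {
    stop("matrix has ", ncol(mat), " columns but the basis expects ",
         length(basis$center), call. = FALSE)
  }
  scores <- sweep(mat, 2, basis$center) %*% basis$eigenvectors
  rownames(scores) <- subject_ids
  structure(list(scores = scores, subject_ids = subject_ids, group = group),
            class = "reduced_feature_set")
}
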