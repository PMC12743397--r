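#' Pointwise two-sample t-statistic trajectory
#'
#' Pooled-variance two-sample t at each timepoint of the stance grid,
#' `groupA` minus `groupB`; swapping the groups flips the sign.
#'
#' @param groupA,groupB Matrices `[n x T]`, one subject-mean waveform per
#'   row, at least two rows each.
#' @return Numeric vector of length T.
#' @export
t_trajectory_unpaired <- function(groupA, groupB) {
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  n1 <- nrow(groupA)
  n2 <- nrow(groupB)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group",
                             call. = FALSE)
  if (ncol(groupA) != ncol(groupB)) stop("time grids differ", call. = FALSE)
  m1 <- colMeans(groupA)
  m2 <- colMeans(groupB)
  ss1 <- colSums(groupA^2) - n1 * m1^2
  ss2 <- colSums(groupB^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  scale <- mean(colMeans(groupA^2) + colMeans(groupB^2))
  zero <- sp2 <= .Machine$double.eps * max(scale, 1)
  if (any(zero)) {
    stop("zero pooled variance at timepoint(s) ",
         paste(which(zero)[seq_len(min(3, sum(zero)))] - 1L, collapse = ", "),
         call. = FALSE)
  }
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Pointwise paired t-statistic trajectory
#'
#' One-sample t of the paired differences (`post - pre`) at each timepoint;
#' subjects must be in matching row order. If the differences are exactly
#' zero everywhere at a timepoint the statistic is 0 there; a degenerate
#' timepoint with zero difference variance but nonzero mean is an error.
#'
#' @param pre,post Matrices `[n x T]` in matched subject order, n >= 2.
#' @return Numeric vector of length T.
#' @export
t_trajectory_paired <- function(pre, post) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) {
    stop("pre and post must have identical dimensions (matched subjects)",
         call. = FALSE)
  }
  n <- nrow(pre)
  if (n < 2) stop("need at least 2 paired subjects", call. = FALSE)
  d <- post - pre
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v <- pmax(v, 0)
  scale <- max(mean(colMeans(d^2)), .Machine$double.eps)
  zero <- v <= .Machine$double.eps * scale
  bad <- zero & abs(m) > sqrt(.Machine$double.eps) * sqrt(scale)
  if (any(bad)) {
    stop("zero difference variance with nonzero mean at timepoint(s) ",
         paste(which(bad)[seq_len(min(3, sum(bad)))] - 1L, collapse = ", "),
         call. = FALSE)
  }
  t <- numeric(length(m))
  ok <- !zero
  t[ok] <- m[ok] / sqrt(v[ok] / n)
  t
}

row_abs_max <- function(x) {
  ax <- abs(x)
  ax[cbind(seq_len(nrow(ax)), max.col(ax, ties.method = "first"))]
}

t_stats_unpaired_batch <- function(g1_indicator, x, n1, n2) {
  # g1_indicator: [B x n] 0/1 membership of group 1; x: [n x T]
  s <- colSums(x)
  sstot <- colSums(x^2)
  s1 <- g1_indicator %*% x
  ss1 <- g1_indicator %*% (x^2)
  m1 <- s1 / n1
  m2 <- sweep(-s1, 2, s, `+`) / n2
  v1 <- ss1 - n1 * m1^2
  v2 <- sweep(-ss1, 2, sstot, `+`) - n2 * m2^2
  sp2 <- pmax(v1 + v2, 0) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  num <- m1 - m2
  t <- num / se
  t[se == 0] <- 0
  t
}

#' Family-wise critical value by max-statistic permutation
#'
#' Builds the null distribution of the maximum absolute t-statistic over the
#' stance grid under group-label permutation (unpaired design) or random
#' sign flips of the paired differences (paired design), and returns the
#' `1 - alpha` empirical quantile. All distinct permutations are enumerated
#' exhaustively when there are at most `n_perm` of them; otherwise `n_perm`
#' random permutations including the observed one are used. A waveform
#' timepoint is then declared significant when its observed `|t|` reaches
#' this critical value, which controls the family-wise error across the
#' whole trajectory.
#'
#' @param groupA,groupB Matrices `[n x T]`; for the paired design these are
#'   `pre` and `post` in matched order.
#' @param design `"unpaired"` or `"paired"`.
#' @param alpha Two-sided family-wise level in (0, 0.5].
#' @param n_perm Permutation budget (default 1000).
#' @param seed Integer seed for random permutations.
#' @return Critical value (numeric scalar) with attributes
#'   `n_permutations` (rows of the null set) and `exhaustive`.
#' @export
permutation_critical_value <- function(groupA, groupB,
                                       design = c("unpaired", "paired"),
                                       alpha = 0.05, n_perm = 1000L,
                                       seed = 1L) {
  design <- match.arg(design)
  if (alpha <= 0 || alpha > 0.5) {
    stop("alpha must lie in (0, 0.5]", call. = FALSE)
  }
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  if (design == "unpaired") {
    n1 <- nrow(groupA)
    n2 <- nrow(groupB)
    n <- n1 + n2
    x <- rbind(groupA, groupB)
    total <- choose(n, n1)
    if (total < 10) {
      stop("fewer than 10 distinct permutations (", total,
           "); not enough units to permute", call. = FALSE)
    }
    if (total <= n_perm) {
      sets <- utils::combn(n, n1)
      g <- matrix(0, ncol(sets), n)
      g[cbind(rep(seq_len(ncol(sets)), each = n1), as.vector(sets))] <- 1
      exhaustive <- TRUE
    } else {
      set.seed(seed)
      g <- matrix(0, n_perm, n)
      g[1, seq_len(n1)] <- 1  # observed labeling
      for (b in 2:n_perm) g[b, sample.int(n, n1)] <- 1
      exhaustive <- FALSE
    }
    t <- t_stats_unpaired_batch(g, x, n1, n2)
  } else {
    if (!all(dim(groupA) == dim(groupB))) {
      stop("paired design needs matched pre/post matrices", call. = FALSE)
    }
    d <- groupB - groupA
    n <- nrow(d)
    total <- 2^n
    if (total < 10) {
      stop("fewer than 10 distinct sign-flip patterns (", total,
           "); not enough units to permute", call. = FALSE)
    }
    if (total <= n_perm) {
      s <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      exhaustive <- TRUE
    } else {
      set.seed(seed)
      s <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      s[1, ] <- 1  # observed signs
      exhaustive <- FALSE
    }
    m <- (s %*% d) / n
    ssd <- colSums(d^2)
    v <- pmax(sweep(-n * m^2, 2, ssd, `+`), 0) / (n - 1)
    se <- sqrt(v / n)
    t <- m / se
    t[se == 0] <- 0
  }
  maxs <- row_abs_max(t)
  crit <- as.numeric(stats::quantile(maxs, 1 - alpha, type = 1))
  structure(crit, n_permutations = nrow(t), exhaustive = exhaustive)
}

#' Summarize a t-trajectory against a critical value
#'
#' @param t_trajectory Numeric vector of pointwise t-statistics.
#' @param critical_value Family-wise critical value.
#' @param channel Optional channel name carried into the result.
#' @return Object of class `spm_result`: `channel`, `t_trajectory`,
#'   `critical_value`, `significant_mask`, `significant_fraction` (percent
#'   of timepoints with `|t| >= critical_value`), and `regions`, a two-column
#'   matrix of 0-based half-open `[start, end)` intervals of maximal
#'   significant runs.
#' @export
spm_summarize <- function(t_trajectory, critical_value, channel = NA) {
  mask <- abs(t_trajectory) >= as.numeric(critical_value)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  regions <- cbind(start = starts[r$values], end = ends[r$values])
  structure(list(channel = channel,
                 t_trajectory = t_trajectory,
                 critical_value = as.numeric(critical_value),
                 significant_mask = mask,
                 significant_fraction = 100 * mean(mask),
                 regions = regions),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat("spm_result", if (!is.na(x$channel)) paste0("[", x$channel, "]"),
      ": |t| >=", sprintf("%.3f", x$critical_value), "over",
      sprintf("%.1f%%", x$significant_fraction), "of the stance phase (",
      nrow(x$regions), "region(s))\n")
  invisible(x)
}

#' Compare two cohorts channel by channel with permutation SPM
#'
#' Computes the pointwise t-trajectory and the max-statistic permutation
#' critical value per channel and summarizes significant regions.
#'
#' @param groupA,groupB Arrays `[subject x channel x timepoint]` of
#'   standardized or raw subject-mean waveforms; for the paired design rows
#'   must be matched.
#' @param channels Channel names to test (default all in `groupA`).
#' @inheritParams permutation_critical_value
#' @return Named list of `spm_result`, one per channel.
#' @export
spm_compare <- function(groupA, groupB, design = c("unpaired", "paired"),
                        channels = NULL, alpha = 0.05, n_perm = 1000L,
                        seed = 1L) {
  design <- match.arg(design)
  stopifnot(length(dim(groupA)) == 3, length(dim(groupB)) == 3)
  all_ch <- dimnames(groupA)[[2]]
  if (is.null(channels)) channels <- all_ch
  out <- list()
  for (i in seq_along(channels)) {
    ch <- channels[i]
    a <- groupA[, ch, , drop = TRUE]
    b <- groupB[, ch, , drop = TRUE]
    t <- if (design == "unpaired") t_trajectory_unpaired(a, b) else
      t_trajectory_paired(a, b)
    crit <- permutation_critical_value(a, b, design, alpha, n_perm,
                                       seed = seed + i)
    out[[ch]] <- spm_summarize(t, crit, channel = ch)
  }
  out
}
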