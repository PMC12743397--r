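#' Choose the number of clusters from a Ward dendrogram
#'
#' Builds the Ward linkage (Euclidean distances, `ward.D2`) on the
#' principal-component scores and returns the k in `[k_min, k_max]`
#' maximizing the relative merge-height gap
#' `g(k) = (h_k - h_{k+1}) / h_{k+1}`, where `h_k` is the fusion height
#' joining k clusters into k - 1. A large gap means the dendrogram resists
#' merging below k clusters. Ties break toward smaller k.
#'
#' @param scores Numeric matrix `[N x P]` (or a `reduced_feature_set`).
#' @param k_min,k_max Search range; requires `N > k_max`.
#' @return Integer k, with attributes `gaps` and `heights` for audit.
#' @export
ward_select_k <- function(scores, k_min = 2L, k_max = 10L) {
  scores <- as_scores(scores)
  n <- nrow(scores)
  if (n <= k_max) {
    stop("need more observations (", n, ") than k_max (", k_max, ")",
         call. = FALSE)
  }
  stopifnot(k_min >= 1, k_min <= k_max)
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  h <- hc$height                       # ascending, length n - 1
  fusion <- function(k) h[n - k + 1L]  # height joining k clusters -> k - 1
  ks <- k_min:k_max
  gaps <- vapply(ks, function(k) {
    (fusion(k) - fusion(k + 1L)) / fusion(k + 1L)
  }, numeric(1))
  k <- ks[which.max(gaps)]             # which.max takes the first (smaller k)
  structure(as.integer(k), gaps = stats::setNames(gaps, ks),
            heights = h)
}

as_scores <- function(x) {
  if (inherits(x, "reduced_feature_set")) x <- x$scores
  as.matrix(x)
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    i <- if (sum(d2) > 0) {
      sample.int(n, 1L, prob = d2 / sum(d2))
    } else {
      sample.int(n, 1L)
    }
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# Exact maximum-agreement assignment between two labelings: returns p with
# p[j] = reference label matched to label j, maximizing sum_j C[p[j], j].
# Branch-and-bound over permutations; k is small (<= 10) in practice.
match_labels <- function(conf) {
  k <- nrow(conf)
  best <- -Inf
  bestp <- integer(k)
  colmax <- apply(conf, 2, max)
  rec <- function(j, used, cur, p) {
    if (j > k) {
      if (cur > best) {
        best <<- cur
        bestp <<- p
      }
      return(invisible(NULL))
    }
    if (cur + sum(colmax[j:k]) <= best) return(invisible(NULL))
    for (i in order(conf[, j], decreasing = TRUE)) {
      if (!used[i]) {
        used[i] <- TRUE
        rec(j + 1L, used, cur + conf[i, j], c(p, i))
        used[i] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, k), 0, integer(0))
  bestp
}

#' Assign subjects to subpopulations by repeated k-means with a
#' consistency filter
#'
#' Runs k-means (Euclidean, k-means++ seeding; run r uses seed `seed + r`)
#' `n_runs` times, aligns the labels of runs 2..n to run 1 by
#' maximum-agreement bipartite matching on the confusion matrix, and marks a
#' subject consistent iff all aligned runs agree on its label; inconsistent
#' subjects are excluded (label `NA`). Clusters are renumbered 1..k by
#' decreasing size (ties by the smallest contained subject id). Silhouette
#' values are computed for consistent subjects when at least two clusters
#' remain.
#'
#' @param scores Matrix `[N x P]` or `reduced_feature_set`.
#' @param k Number of clusters (>= 2).
#' @param n_runs Number of k-means repetitions (default 5).
#' @param seed Integer base seed.
#' @param n_starts Restarts within each run (default 5): each run keeps the
#'   best of `n_starts` k-means++ initializations by total within-cluster
#'   sum of squares, so a run reports its best local optimum and the
#'   consistency filter measures genuine ambiguity rather than unlucky
#'   starts.
#' @param subject_ids Optional subject identifiers (default row names or
#'   `s1..sN`).
#' @return Data frame of class `subpop_assignment`: `subject_id`, `label`
#'   (integer in 1..k or `NA` for excluded), `consistent` (logical),
#'   `silhouette` (`NA` for excluded).
#' @export
kmeans_consensus <- function(scores, k, n_runs = 5L, seed = 1L,
                             n_starts = 5L, subject_ids = NULL) {
  scores <- as_scores(scores)
  n <- nrow(scores)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")",
                  call. = FALSE)
  if (n_runs < 1) stop("n_runs must be at least 1", call. = FALSE)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(scores)
    if (is.null(subject_ids)) subject_ids <- sprintf("s%d", seq_len(n))
  }

  labels <- matrix(NA_integer_, n, n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    best <- NULL
    for (s in seq_len(max(1L, n_starts))) {
      init <- kmeanspp_init(scores, k)
      km <- tryCatch(
        stats::kmeans(scores, centers = init, iter.max = 100L),
        error = function(e) stats::kmeans(scores, centers = init,
                                          iter.max = 100L,
                                          algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    labels[, r] <- best$cluster
  }
  # align every run to run 1
  for (r in seq_len(n_runs)[-1L]) {
    conf <- matrix(0L, k, k)
    tab <- table(factor(labels[, 1L], levels = 1:k),
                 factor(labels[, r], levels = 1:k))
    conf[] <- tab
    p <- match_labels(conf)
    labels[, r] <- p[labels[, r]]
  }
  consistent <- apply(labels, 1, function(z) length(unique(z)) == 1L)
  lab <- ifelse(consistent, labels[, 1L], NA_integer_)

  # canonical renumbering: decreasing size, ties by smallest subject_id
  present <- sort(unique(lab[!is.na(lab)]))
  if (length(present)) {
    sizes <- vapply(present, function(g) sum(lab == g, na.rm = TRUE),
                    integer(1))
    firsts <- vapply(present, function(g) {
      min(subject_ids[!is.na(lab) & lab == g])
    }, character(1))
    ord <- present[order(-sizes, firsts)]
    lab <- match(lab, ord)
  }

  sil <- rep(NA_real_, n)
  ok <- !is.na(lab)
  if (sum(ok) >= 2 && length(unique(lab[ok])) >= 2) {
    sil[ok] <- silhouette_values(scores[ok, , drop = FALSE], lab[ok])
  }
  structure(data.frame(subject_id = subject_ids,
                       label = lab,
                       consistent = consistent,
                       silhouette = sil,
                       stringsAsFactors = FALSE),
            class = c("subpop_assignment", "data.frame"))
}

#' Silhouette values for a clustering
#'
#' Classic silhouette `s = (b - a) / max(a, b)` with Euclidean distances,
#' where `a` is the mean within-cluster distance and `b` the mean distance
#' to the nearest other cluster; members of singleton clusters get 0.
#'
#' @param scores Matrix `[N x P]` or `reduced_feature_set`.
#' @param labels Integer cluster labels (no `NA`); at least two distinct
#'   clusters required.
#' @return Numeric vector of silhouette values in input order.
#' @export
silhouette_values <- function(scores, labels) {
  scores <- as_scores(scores)
  stopifnot(length(labels) == nrow(scores), !anyNA(labels))
  if (length(unique(labels)) < 2) {
    stop("silhouettes require at least two clusters", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(labels), stats::dist(scores))
  as.numeric(sil[, "sil_width"])
}
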