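# Independent oracles used to check implementation paths.

# Dual SVM solved by a plain SMO loop (pairwise coordinate ascent on the
# box-constrained dual with the equality constraint). Independent of libsvm.
smo_linear_svm <- function(x, y, C = 1, max_pass = 5000, tol = 1e-12) {
  n <- nrow(x)
  K <- tcrossprod(x)
  alpha <- rep(0, n)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      g <- drop(K %*% (alpha * y))      # decision values without bias
      e_i <- g[i] - y[i]
      e_j <- g[j] - y[j]
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 0) next
      if (y[i] != y[j]) {
        lo <- max(0, alpha[j] - alpha[i])
        hi <- min(C, C + alpha[j] - alpha[i])
      } else {
        lo <- max(0, alpha[i] + alpha[j] - C)
        hi <- min(C, alpha[i] + alpha[j])
      }
      if (lo >= hi) next
      aj <- alpha[j] + y[j] * (e_i - e_j) / eta
      aj <- min(max(aj, lo), hi)
      if (abs(aj - alpha[j]) > tol) {
        alpha[i] <- alpha[i] + y[i] * y[j] * (alpha[j] - aj)
        alpha[j] <- aj
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  w <- drop(t(x) %*% (alpha * y))
  on_margin <- which(alpha > 1e-8 & alpha < C - 1e-8)
  b <- if (length(on_margin)) {
    mean(y[on_margin] - x[on_margin, , drop = FALSE] %*% w)
  } else {
    -(max((x %*% w)[y == -1]) + min((x %*% w)[y == 1])) / 2
  }
  list(w = w, b = b, alpha = alpha)
}

svm_primal_objective <- function(w, b, x, y, C) {
  margins <- y * (drop(x %*% w) + b)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - margins))
}

# Exact Shapley values by enumeration over all feature coalitions, with
# mean imputation of absent features, for an arbitrary value function.
brute_force_shapley <- function(f, x, background) {
  p <- length(x)
  idx <- seq_len(p)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  v <- function(mask) {
    z <- background
    z[mask] <- x[mask]
    f(z)
  }
  for (i in idx) {
    for (r in seq_len(nrow(subsets))) {
      s <- unlist(subsets[r, ])
      if (s[i]) next
      size <- sum(s)
      weight <- factorial(size) * factorial(p - size - 1) / factorial(p)
      s_with <- s
      s_with[i] <- TRUE
      phi[i] <- phi[i] + weight * (v(s_with) - v(s))
    }
  }
  phi
}

# Adjusted Rand index (independent of mclust, used when comparing labelings)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Smooth correlated noise curves used by the SPM calibration checks.
smooth_noise <- function(n, nt = 101, lengthscale = 0.3, sd = 1) {
  grid <- seq(0, 1, length.out = nt)
  k <- exp(-0.5 * (outer(grid, grid, `-`) / lengthscale)^2)
  L <- chol(k + diag(1e-8, nt))
  t(crossprod(L, matrix(rnorm(nt * n), nt, n))) * sd
}
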