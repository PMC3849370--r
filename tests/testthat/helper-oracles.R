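# Independent oracles used to check the implementation.  Each recomputes its
# quantity from first principles (brute-force loops, closed forms,
# enumeration) without sharing code with the package internals.

# Step-by-step greedy ORMP: projections recomputed from scratch each step via
# least squares on the current support.
oracle_ormp <- function(d, x, s) {
  supp <- integer(0)
  proj_resid <- function(v, cols) {
    if (!length(cols)) return(v)
    a <- d[, cols, drop = FALSE]
    v - a %*% qr.solve(a, v)
  }
  for (step in seq_len(s)) {
    r <- proj_resid(x, supp)
    best <- -Inf
    best_k <- 0L
    for (k in seq_len(ncol(d))) {
      if (k %in% supp) next
      dperp <- proj_resid(d[, k], supp)
      nd <- sqrt(sum(dperp^2))
      if (nd < 1e-8) next
      sc <- abs(sum(r * d[, k])) / nd
      if (sc > best) {
        best <- sc
        best_k <- k
      }
    }
    if (best_k == 0L) break
    supp <- c(supp, best_k)
  }
  w <- qr.solve(d[, supp, drop = FALSE], x)
  res <- x - d[, supp, drop = FALSE] %*% w
  list(support = supp, residual_norm = sqrt(sum(res^2)))
}

# Exhaustive best 2-atom residual via the closed-form 2x2 normal equations.
oracle_best_pair_residual <- function(d, x) {
  g <- crossprod(d)
  b <- drop(crossprod(d, x))
  x2 <- sum(x^2)
  k_n <- ncol(d)
  best <- Inf
  for (i in seq_len(k_n - 1L)) {
    for (j in (i + 1L):k_n) {
      det_g <- g[i, i] * g[j, j] - g[i, j]^2
      if (det_g < 1e-12) next
      r2 <- x2 - (g[j, j] * b[i]^2 - 2 * g[i, j] * b[i] * b[j] +
                    g[i, i] * b[j]^2) / det_g
      best <- min(best, r2)
    }
  }
  sqrt(max(best, 0))
}

# Naive double-loop sliding mean.
oracle_dc <- function(image, n) {
  h <- (n - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(image), ncol(image))
  for (i in (1 + h):(nrow(image) - h)) {
    for (j in (1 + h):(ncol(image) - h)) {
      out[i, j] <- mean(image[(i - h):(i + h), (j - h):(j + h)])
    }
  }
  out
}

# Exhaustive enumeration of all group-label assignments for the two-sided
# Mann-Whitney p, with the half-tie U convention.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- utils::combn(n, n1, u_of)
  p <- 2 * min(mean(all_u <= u_obs + 1e-9), mean(all_u >= u_obs - 1e-9))
  list(statistic = u_obs, p_value = min(p, 1))
}

# Shoelace polygon area.
oracle_polygon_area <- function(poly) {
  x <- poly[, 2]
  y <- poly[, 1]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Brute-force count of pixels whose full n x n window lies inside `mask`.
oracle_pure_window_count <- function(mask, n) {
  h <- (n - 1L) %/% 2L
  cnt <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (i - h < 1 || i + h > nrow(mask) || j - h < 1 || j + h > ncol(mask)) next
      if (all(mask[(i - h):(i + h), (j - h):(j + h)])) cnt <- cnt + 1L
    }
  }
  cnt
}
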