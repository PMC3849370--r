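# Sparse representation machinery: order recursive matching pursuit (ORMP)
# coding, online dictionary learning by recursive least squares (RLS-DLA) with
# a forgetting-factor ramp, and the atom first-derivative statistic used to
# compare scar and healthy dictionaries.
#
# A dictionary D is an N x K matrix of unit-norm atoms with K > N; a signal x
# (a vectorized image patch) is approximated as x ~ D w with at most s nonzero
# coefficients, and the representation error ||x - D w|| is the quantity that
# discriminates textures: a patch is "explained" best by the dictionary
# trained on its own texture class.

#' Construct a texture dictionary object
#'
#' @param atoms N x K numeric matrix, one atom per column.
#' @param class_role which texture class the dictionary represents:
#'   `"scar"`, `"myo"` or `"other"`.
#' @param remove_dc was the dictionary trained on mean-subtracted patches?
#' @param normalized assert unit atom norms (within 1e-9)?
#' @return The matrix with class `"texture_dictionary"` and the metadata as
#'   attributes.
#' @export
texture_dictionary <- function(atoms, class_role = c("other", "scar", "myo"),
                               remove_dc = FALSE, normalized = TRUE) {
  class_role <- match.arg(class_role)
  atoms <- as.matrix(atoms)
  if (normalized) {
    nrm <- sqrt(colSums(atoms^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("dictionary atoms must have unit Euclidean norm")
  }
  structure(atoms, class = c("texture_dictionary", "matrix", "array"),
            class_role = class_role, remove_dc = remove_dc)
}

#' @export
print.texture_dictionary <- function(x, ...) {
  cat(sprintf("texture dictionary: %d x %d atoms (class '%s'%s)\n",
              nrow(x), ncol(x), attr(x, "class_role"),
              if (isTRUE(attr(x, "remove_dc"))) ", DC removed" else ""))
  invisible(x)
}

# Greedy ORMP selection core.  Returns list(support, coefficients-on-support).
# At each step the chosen atom maximizes |<r, d_k>| / ||d_k orthogonal to the
# selected span||; ties break to the lowest atom index; atoms numerically
# dependent on the selected span are skipped.  Final coefficients are the
# least-squares solution on the support, so the residual is orthogonal to the
# span of the selected atoms.
ormp_core <- function(d, x, s, tol = 1e-10) {
  n_dim <- nrow(d)
  k_n <- ncol(d)
  if (sum(x^2) == 0) return(list(support = integer(0), coef = numeric(0)))
  s <- min(s, n_dim)
  atom_nrm2 <- colSums(d^2)
  proj2 <- numeric(k_n)            # squared projections onto the selected span
  c_r <- drop(crossprod(d, x))     # <d_k, r>, maintained incrementally
  q_mat <- matrix(0, n_dim, s)
  support <- integer(0)
  for (step in seq_len(s)) {
    dperp2 <- atom_nrm2 - proj2
    score <- abs(c_r) / sqrt(pmax(dperp2, .Machine$double.eps))
    score[support] <- -Inf
    score[dperp2 < tol] <- -Inf
    k <- which.max(score)
    if (!is.finite(score[k]) || score[k] <= 0) break
    q <- d[, k]
    if (step > 1L) {
      qs <- q_mat[, seq_len(step - 1L), drop = FALSE]
      q <- q - qs %*% crossprod(qs, q)
    }
    qn <- sqrt(sum(q^2))
    if (qn < tol) break
    q <- q / qn
    q_mat[, step] <- q
    support <- c(support, k)
    qa <- drop(crossprod(d, q))
    proj2 <- proj2 + qa^2
    c_r <- c_r - qa * sum(q * x)
  }
  if (!length(support)) return(list(support = integer(0), coef = numeric(0)))
  w <- qr.coef(qr(d[, support, drop = FALSE]), x)
  list(support = support, coef = as.numeric(w))
}

#' Order recursive matching pursuit sparse coding
#'
#' Greedy sparse approximation of `signal` with at most `sparsity` atoms of
#' `dictionary`: at each step the atom whose component orthogonal to the
#' already-selected span carries the largest residual projection is added, and
#' the coefficients are re-solved by least squares on the selected support.
#' The residual norm is non-increasing in `sparsity`.
#'
#' @param dictionary N x K matrix (see [texture_dictionary()]).
#' @param signal numeric vector of length N.
#' @param sparsity maximum number of nonzero coefficients, `1 <= s <= N`.
#' @return An object of class `"sparse_code"`: a list with `coefficients`
#'   (length-K, zeros off support), `support`, `approximation` (`D %*% w`) and
#'   `residual_norm`.
#' @export
ormp <- function(dictionary, signal, sparsity) {
  d <- unclass(dictionary)
  x <- as.numeric(signal)
  if (length(x) != nrow(d))
    stop("signal length ", length(x), " does not match atom length ", nrow(d))
  if (sparsity < 1 || sparsity > nrow(d))
    stop("sparsity must lie in [1, ", nrow(d), "]")
  sel <- ormp_core(d, x, sparsity)
  w <- numeric(ncol(d))
  w[sel$support] <- sel$coef
  approx_x <- if (length(sel$support))
    drop(d[, sel$support, drop = FALSE] %*% sel$coef) else numeric(length(x))
  structure(list(coefficients = w, support = sel$support,
                 approximation = approx_x,
                 residual_norm = sqrt(sum((x - approx_x)^2))),
            class = "sparse_code")
}

# Residual norms of many signals (columns of x) against one dictionary.
# Same selection core as ormp(), looped over columns.
ormp_residual_norms <- function(d, x, sparsity) {
  d <- unclass(d)
  out <- numeric(ncol(x))
  for (m in seq_len(ncol(x))) {
    xm <- x[, m]
    sel <- ormp_core(d, xm, sparsity)
    r <- if (length(sel$support))
      xm - d[, sel$support, drop = FALSE] %*% sel$coef else xm
    out[m] <- sqrt(sum(r^2))
  }
  out
}

#' Initialize the state of the recursive dictionary learner
#'
#' @param dictionary initial N x K dictionary.
#' @param lambda0 initial forgetting factor (1 = no forgetting).
#' @param tau e-folding time of the forgetting-factor ramp, in training steps;
#'   `lambda_t = 1 - (1 - lambda0) * exp(-t / tau)`.
#' @return An object of class `"rls_state"`: list with `dictionary`, `C`
#'   (K x K, initialized to the identity), step counter `t` and the ramp
#'   parameters.
#' @export
rls_state <- function(dictionary, lambda0 = 1, tau = Inf) {
  d <- as.matrix(dictionary)
  structure(list(dictionary = d, C = diag(ncol(d)), t = 0L,
                 lambda0 = lambda0, tau = tau),
            class = "rls_state")
}

#' Forgetting factor at a given training step
#'
#' Exponential ramp from `lambda0` toward 1: old observations are discounted
#' early in training (helping the dictionary escape its initialization) and
#' fully retained asymptotically.
#'
#' @param t step counter (1-based).
#' @param lambda0 initial forgetting factor.
#' @param tau ramp time constant in steps (`Inf` freezes lambda at `lambda0`).
#' @return The forgetting factor `lambda_t` in `(0, 1]`.
#' @export
forgetting_factor <- function(t, lambda0, tau = Inf) {
  if (!is.finite(tau)) return(lambda0)
  1 - (1 - lambda0) * exp(-t / tau)
}

#' One recursive least squares dictionary update
#'
#' Given the sparse code `w` of `signal` against the current dictionary, the
#' rank-one update with forgetting factor `lambda_t` is
#' `u = (C / lambda) w`, `alpha = 1 / (1 + w'u)`, `r = x - D w`,
#' `C <- C / lambda - alpha u u'`, `D <- D + alpha r u'`.
#' A perfectly represented signal (`r = 0`) leaves the dictionary unchanged.
#'
#' @param state an [rls_state()].
#' @param signal the training vector just coded.
#' @param code its [ormp()] code against `state$dictionary`.
#' @return The updated `"rls_state"` (step counter incremented).
#' @export
rlsdla_step <- function(state, signal, code) {
  stopifnot(inherits(state, "rls_state"), inherits(code, "sparse_code"))
  t_new <- state$t + 1L
  lam <- forgetting_factor(t_new, state$lambda0, state$tau)
  w <- code$coefficients
  u <- drop(state$C %*% w) / lam
  denom <- 1 + sum(w * u)
  alpha <- 1 / denom
  if (!is.finite(alpha) || denom == 0)
    stop(sprintf("RLS update degenerate at step %d: 1 + w'u = %g", t_new, denom))
  r <- signal - drop(state$dictionary %*% w)
  state$C <- state$C / lam - alpha * tcrossprod(u)
  state$dictionary <- state$dictionary + alpha * tcrossprod(r, u)
  state$t <- t_new
  state
}

#' Train a texture dictionary with RLS-DLA
#'
#' Online dictionary learning: the initial dictionary is `K` distinct training
#' vectors drawn with `seed` and normalized; in each epoch the training
#' vectors are visited in a seeded shuffle, each is ORMP-coded against the
#' current dictionary and applied through [rlsdla_step()], with the forgetting
#' factor ramping from `lambda0` toward 1.  Atoms are renormalized and `C`
#' reset at epoch boundaries only, so the rank-one recursion is exact within a
#' pass.  The result is bit-reproducible given (training set, seed).
#'
#' @param training a `"training_set"` (see [collect_training_vectors()]) or an
#'   N x L matrix of training vectors.
#' @param K number of atoms; must exceed the patch dimension N.
#' @param sparsity target sparsity used during coding (default 2).
#' @param epochs passes over the training set.
#' @param lambda0 initial forgetting factor (default 0.995).
#' @param tau ramp time constant; default `epochs * L / 5`.
#' @param seed integer seed for initialization and shuffling.
#' @param class_role stored on the returned dictionary.
#' @param remove_dc stored on the returned dictionary (the caller is
#'   responsible for having mean-subtracted the training vectors).
#' @return A [texture_dictionary()] with unit-norm atoms.
#' @export
train_dictionary <- function(training, K = 90L, sparsity = 2L, epochs = 40L,
                             lambda0 = 0.995, tau = NULL, seed = 1L,
                             class_role = "other", remove_dc = FALSE) {
  x <- if (inherits(training, "training_set")) training$vectors else as.matrix(training)
  n_dim <- nrow(x)
  l_n <- ncol(x)
  if (K <= n_dim)
    stop("K (", K, ") must exceed the patch dimension N (", n_dim, ")")
  if (l_n < K)
    stop("need at least K = ", K, " training vectors, got ", l_n)
  if (is.null(tau)) tau <- epochs * l_n / 5
  set.seed(seed)
  d <- x[, sample.int(l_n, K), drop = FALSE]
  nrm <- sqrt(colSums(d^2))
  nrm[nrm == 0] <- 1
  d <- sweep(d, 2L, nrm, "/")
  state <- rls_state(d, lambda0 = lambda0, tau = tau)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(l_n)
    for (i in ord) {
      xi <- x[, i]
      sel <- ormp_core(state$dictionary, xi, sparsity)
      w <- numeric(K)
      w[sel$support] <- sel$coef
      code <- structure(list(coefficients = w, support = sel$support),
                        class = "sparse_code")
      state <- rlsdla_step(state, xi, code)
    }
    nrm <- sqrt(colSums(state$dictionary^2))
    nrm[nrm < 1e-12] <- 1
    state$dictionary <- sweep(state$dictionary, 2L, nrm, "/")
    state$C <- diag(K)
  }
  texture_dictionary(state$dictionary, class_role = class_role,
                     remove_dc = remove_dc)
}

#' Mean absolute first derivative of the dictionary atoms
#'
#' Each atom is reshaped to its patch (row-major order), first differences are
#' taken along rows and along columns, and the statistic is the mean absolute
#' difference pooled over all atoms.  Smooth, intensity-offset-dominated atoms
#' (dictionaries trained with the patch mean retained) score low; atoms that
#' carry fine spatial variation score high, so the statistic summarizes how
#' much texture, as opposed to plain intensity, a dictionary has captured.
#'
#' @param dictionary a [texture_dictionary()] or plain matrix.
#' @param patch_shape integer length-2, the patch shape `(N, N)`; the atom
#'   length must equal `prod(patch_shape)`.
#' @return A nonnegative scalar; 0 for all-constant atoms, invariant to atom
#'   sign flips.
#' @export
atom_derivative_statistic <- function(dictionary,
                                      patch_shape = rep(round(sqrt(nrow(dictionary))), 2)) {
  d <- unclass(dictionary)
  if (prod(patch_shape) != nrow(d))
    stop("atom length ", nrow(d), " is not the product of patch_shape")
  diffs <- unlist(lapply(seq_len(ncol(d)), function(k) {
    a <- matrix(d[, k], patch_shape[1], patch_shape[2], byrow = TRUE)
    c(if (ncol(a) > 1) a[, -1, drop = FALSE] - a[, -ncol(a), drop = FALSE],
      if (nrow(a) > 1) a[-1, , drop = FALSE] - a[-nrow(a), , drop = FALSE])
  }))
  mean(abs(diffs))
}

#' Serialize a dictionary to JSON or delimited text
#'
#' @param dictionary a [texture_dictionary()].
#' @param path output file; `.json` or `.tsv` by extension.
#' @export
write_dictionary <- function(dictionary, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(list(n = nrow(dictionary), k = ncol(dictionary),
                              class_role = attr(dictionary, "class_role"),
                              remove_dc = isTRUE(attr(dictionary, "remove_dc")),
                              order = "column-per-atom",
                              atoms = unclass(dictionary)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(unclass(dictionary), path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    texture_dictionary(matrix(obj$atoms, obj$n, obj$k),
                       class_role = obj$class_role, remove_dc = obj$remove_dc,
                       normalized = FALSE)
  } else {
    texture_dictionary(as.matrix(utils::read.table(path, sep = "\t")),
                       normalized = FALSE)
  }
}
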