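random_dictionary <- function(n, k, seed) {
  set.seed(seed)
  d <- matrix(stats::rnorm(n * k), n, k)
  sweep(d, 2, sqrt(colSums(d^2)), "/")
}

test_that("ORMP recovers exact atoms and reaches zero residual at full rank", {
  d <- random_dictionary(9, 20, 1)
  code <- ormp(d, d[, 3], sparsity = 1)
  expect_identical(code$support, 3L)
  expect_lt(code$residual_norm, 1e-12)

  set.seed(2)
  x <- stats::rnorm(9)
  full <- ormp(d, x, sparsity = 9)
  expect_lt(full$residual_norm, 1e-9)

  zero <- ormp(d, numeric(9), sparsity = 2)
  expect_equal(zero$coefficients, numeric(20))
  expect_equal(zero$residual_norm, 0)

  expect_error(ormp(d, numeric(5), 2), "length")
  expect_error(ormp(d, x, 0), "sparsity")
})

test_that("ORMP matches the from-scratch greedy oracle and respects optimality bounds", {
  for (seed in 1:60) {
    d <- random_dictionary(9, 20, 100 + seed)
    set.seed(200 + seed)
    x <- stats::rnorm(9)
    code <- ormp(d, x, sparsity = 2)
    orc <- oracle_ormp(d, x, 2)
    expect_identical(code$support, orc$support)
    expect_equal(code$residual_norm, orc$residual_norm, tolerance = 1e-10)
    # greedy can never beat the exhaustive best pair
    expect_gte(code$residual_norm, oracle_best_pair_residual(d, x) - 1e-9)
    # residual orthogonal to the selected span
    r <- x - code$approximation
    expect_lt(max(abs(crossprod(d[, code$support, drop = FALSE], r))), 1e-8)
  }
})

test_that("ORMP residuals are non-increasing in the sparsity target", {
  for (seed in 1:10) {
    d <- random_dictionary(9, 25, 300 + seed)
    set.seed(400 + seed)
    x <- stats::rnorm(9)
    res <- vapply(1:9, function(s) ormp(d, x, s)$residual_norm, 0)
    expect_true(all(diff(res) <= 1e-10))
  }
})

test_that("the RLS update reproduces the hand-worked single step", {
  state <- rls_state(diag(2), lambda0 = 1)
  code <- structure(list(coefficients = c(1, 0), support = 1L),
                    class = "sparse_code")
  out <- rlsdla_step(state, c(1, 1), code)
  expect_equal(out$dictionary, matrix(c(1, 0.5, 0, 1), 2, 2))
  expect_equal(out$C, diag(c(0.5, 1)))
  expect_equal(out$t, 1L)

  # a perfectly represented signal leaves the dictionary untouched
  state2 <- rls_state(diag(2), lambda0 = 1)
  code2 <- structure(list(coefficients = c(0, 1), support = 2L),
                     class = "sparse_code")
  out2 <- rlsdla_step(state2, c(0, 1), code2)
  expect_equal(out2$dictionary, diag(2))
})

test_that("with no forgetting the recursion solves the accumulated least squares problem", {
  # The identity-initialized C counts as prior observations (virtual signals
  # D0 with identity codes); the recursion then maintains the exact normal
  # equations D_T (I + W W') = D0 + X W'.
  set.seed(5)
  n <- 4
  k_n <- 6
  l_n <- 40
  d0 <- matrix(stats::rnorm(n * k_n), n, k_n)
  state <- rls_state(d0, lambda0 = 1)
  xs <- matrix(stats::rnorm(n * l_n), n, l_n)
  ws <- matrix(0, k_n, l_n)
  for (i in seq_len(l_n)) {
    code <- ormp(state$dictionary, xs[, i], sparsity = 2)
    ws[, i] <- code$coefficients
    state <- rlsdla_step(state, xs[, i], code)
  }
  lhs <- state$dictionary %*% (diag(k_n) + tcrossprod(ws))
  rhs <- d0 + tcrossprod(xs, ws)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
})

test_that("dictionary training is reproducible and represents its training set", {
  set.seed(6)
  base <- stats::rnorm(9)
  copies <- matrix(base, 9, 30)
  d <- train_dictionary(copies, K = 10, sparsity = 2, epochs = 3, seed = 3)
  resid <- ormp_residual_norms(d, copies, 2)
  expect_lt(mean(resid), 1e-6)
  expect_true(all(abs(sqrt(colSums(unclass(d)^2)) - 1) < 1e-9))

  set.seed(7)
  x <- matrix(stats::rnorm(9 * 40), 9, 40)
  d1 <- train_dictionary(x, K = 12, sparsity = 2, epochs = 2, seed = 9)
  d2 <- train_dictionary(x, K = 12, sparsity = 2, epochs = 2, seed = 9)
  expect_identical(unclass(d1), unclass(d2))

  expect_error(train_dictionary(x, K = 9, sparsity = 2), "exceed")
  expect_error(train_dictionary(x, K = 60, sparsity = 2), "training vectors")
})

test_that("the forgetting factor ramps from lambda0 toward 1", {
  lam <- forgetting_factor(c(1, 10, 1e6), lambda0 = 0.995, tau = 100)
  expect_true(all(diff(lam) > 0))
  expect_lt(abs(lam[3] - 1), 1e-9)
  expect_equal(forgetting_factor(5, 0.9, Inf), 0.9)
})

test_that("the atom derivative statistic measures spatial variation", {
  const <- texture_dictionary(matrix(1 / 3, 9, 12), normalized = TRUE)
  expect_equal(atom_derivative_statistic(const), 0)

  a <- matrix(c(0, 1, 0, 0, 1, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  d1 <- matrix(as.numeric(t(a)), 9, 1)   # row-major vectorization
  expect_equal(atom_derivative_statistic(d1, c(3, 3)), 0.5)
  expect_equal(atom_derivative_statistic(-d1, c(3, 3)), 0.5)
  expect_error(atom_derivative_statistic(matrix(0, 8, 3)), "patch_shape")
})

test_that("DC removal raises the scar dictionary's derivative statistic", {
  # with the patch mean retained, the bright homogeneous scar dominates the
  # atoms (low spatial variation); removing it leaves only texture
  sl <- training_phantoms()[[1]]
  sets <- collect_training_vectors(sl$image, sl$annotation, n = 3)
  sets_nodc <- collect_training_vectors(sl$image, sl$annotation, n = 3,
                                        remove_dc = TRUE)
  d_with <- train_dictionary(sets$scar, K = 30, sparsity = 2, epochs = 10,
                             seed = 2, class_role = "scar")
  d_without <- train_dictionary(sets_nodc$scar, K = 30, sparsity = 2,
                                epochs = 10, seed = 2, class_role = "scar",
                                remove_dc = TRUE)
  expect_lt(atom_derivative_statistic(d_with),
            atom_derivative_statistic(d_without))
})

test_that("dictionaries serialize to JSON and TSV without loss", {
  d <- texture_dictionary(random_dictionary(9, 15, 44), class_role = "scar")
  fj <- withr::local_tempfile(fileext = ".json")
  write_dictionary(d, fj)
  dj <- read_dictionary(fj)
  expect_equal(unclass(dj), unclass(d), ignore_attr = TRUE)
  expect_equal(attr(dj, "class_role"), "scar")

  ft <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(d, ft)
  expect_equal(unclass(read_dictionary(ft)), unclass(d),
               ignore_attr = TRUE, tolerance = 1e-12)
})
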