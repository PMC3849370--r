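as_map <- function(m) structure(m, class = c("probability_map", "matrix", "array"))

test_that("the LU candidate grid enumerates all admissible intervals", {
  g <- lu_grid(step = 0.5, min_width = 0.5)
  expect_equal(g$candidates,
               data.frame(L = c(0, 0, 0.5), U = c(0.5, 1, 1)))

  g2 <- lu_grid(0.025, 0.1)
  # brute-force double loop over the 41-point grid
  brute <- 0L
  for (i in 0:40) for (j in 0:40) {
    if (j * 0.025 - i * 0.025 >= 0.1 - 1e-12) brute <- brute + 1L
  }
  expect_equal(nrow(g2$candidates), brute)
  expect_equal(brute, 703L)
  for (seg in list(c(0.15, 0.3), c(0.3, 0.7), c(0.7, 0.825))) {
    expect_true(any(abs(g2$candidates$L - seg[1]) < 1e-9 &
                    abs(g2$candidates$U - seg[2]) < 1e-9))
  }

  expect_error(lu_grid(0.3, 0.5), "divide")
  expect_error(lu_grid(0.2, 0.1), "step <= min_width")
})

test_that("sigmoid extension is order-preserving and hits its anchors", {
  set.seed(23)
  m <- matrix(NA_real_, 8, 8)
  m[2:7, 2:7] <- stats::runif(36, 0.3, 0.6)
  ext <- sigmoid_extend(as_map(m))
  v <- m[!is.na(m)]
  ve <- ext[!is.na(ext)]
  expect_true(all(diff(ve[order(v)]) > 0))
  expect_equal(min(ve), 0.01, tolerance = 1e-9)
  expect_equal(max(ve), 0.99, tolerance = 1e-9)

  # a map already spanning [0.01, 0.99] symmetric about 0.5 keeps its midpoint
  sym <- matrix(c(0.01, 0.99, 0.5, 0.30, 0.70, NA), 2, 3)
  ext2 <- sigmoid_extend(as_map(sym))
  expect_equal(ext2[1, 2], 0.5)
  expect_equal(ext2[1, 1], 0.01, tolerance = 1e-9)
  expect_equal(ext2[2, 1], 0.99, tolerance = 1e-9)

  expect_warning(sigmoid_extend(as_map(matrix(0.4, 3, 3))), "constant")
})

test_that("relative segment sizes accumulate over slices", {
  m1 <- as_map(matrix(c(0.1, 0.5, 0.9, NA), 2, 2))
  m2 <- as_map(matrix(c(0.5, 1.0, NA, NA), 2, 2))
  maps <- list(m1, m2)

  expect_equal(segment_relative_size(maps, 0, 1), 1)   # inclusive top
  expect_equal(segment_relative_size(list(as_map(matrix(0.5, 4, 4))),
                                     0.7, 0.825), 0)
  # accumulated before dividing: 2 of 5 defined pixels in [0.5, 0.9)
  expect_equal(segment_relative_size(maps, 0.5, 0.9), 2 / 5)

  # brute-force oracle on a seeded map
  set.seed(24)
  mm <- matrix(stats::runif(400), 20, 20)
  mm[1, ] <- NA
  bounds <- c(0.2, 0.65)
  cnt <- 0L
  tot <- 0L
  for (i in 1:20) for (j in 1:20) {
    p <- mm[i, j]
    if (is.na(p)) next
    tot <- tot + 1L
    if (p >= bounds[1] && p < bounds[2]) cnt <- cnt + 1L
  }
  expect_equal(segment_relative_size(list(as_map(mm)), bounds[1], bounds[2]),
               cnt / tot)

  expect_error(segment_relative_size(list(as_map(matrix(NA_real_, 2, 2))), 0, 1),
               "empty")
})

test_that("adjacent half-open segments partition the myocardium and sizes are monotone", {
  set.seed(25)
  m <- as_map(matrix(stats::runif(900), 30, 30))
  edges <- seq(0, 1, by = 0.1)
  sizes <- vapply(seq_len(10), function(k)
    segment_relative_size(list(m), edges[k], edges[k + 1]), 0)
  expect_equal(sum(sizes), 1)

  ls <- vapply(seq(0, 0.4, by = 0.1), function(l)
    segment_relative_size(list(m), l, 0.9), 0)
  expect_true(all(diff(ls) <= 0))      # non-increasing in L
  us <- vapply(seq(0.5, 1, by = 0.1), function(u)
    segment_relative_size(list(m), 0.2, u), 0)
  expect_true(all(diff(us) >= 0))      # non-decreasing in U
})

test_that("the cohort size table matches per-segment recomputation", {
  set.seed(26)
  pm <- lapply(1:3, function(i)
    lapply(1:2, function(j) as_map(matrix(stats::runif(64), 8, 8))))
  names(pm) <- c("a", "b", "c")
  grid <- lu_grid(0.25, 0.25)
  tab <- segment_size_table(pm, c("g1", "g1", "g2"), grid)
  expect_s3_class(tab, "segment_size_table")
  expect_equal(nrow(tab), 3 * nrow(grid$candidates))
  for (r in sample(nrow(tab), 10)) {
    expect_equal(tab$relative_size[r],
                 segment_relative_size(pm[[tab$patient[r]]], tab$L[r], tab$U[r]))
  }
  expect_true(all(tab$relative_size >= 0 & tab$relative_size <= 1))
})

test_that("Mann-Whitney matches exhaustive enumeration for small groups", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  expect_equal(mann_whitney(c(5, 1, 3), c(3, 1, 5))$p_value, 1)

  set.seed(27)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    a <- stats::rnorm(n1)
    b <- stats::rnorm(n2)
    got <- mann_whitney(a, b)
    orc <- oracle_mann_whitney(a, b)
    expect_equal(got$statistic, orc$statistic)
    expect_equal(got$p_value, orc$p_value, tolerance = 1e-9)
    # independent cross-check against the standard implementation
    expect_equal(got$statistic,
                 unname(stats::wilcox.test(a, b, exact = TRUE)$statistic))
  }
})

test_that("the normal-approximation branch is calibrated under the null", {
  set.seed(28)
  reject <- vapply(seq_len(2000), function(i) {
    mann_whitney(stats::rnorm(30), stats::rnorm(30))$p_value < 0.05
  }, NA)
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("the U statistic equals AUC times the number of pairs", {
  set.seed(29)
  for (rep in 1:10) {
    pos <- sample(seq(0, 1, by = 0.1), 15, replace = TRUE)   # many ties
    neg <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)
    r <- roc_auc(c(pos, neg), c(rep(1, 15), rep(0, 12)))
    u <- mann_whitney(pos, neg)$statistic
    expect_equal(r$auc * 15 * 12, u, tolerance = 1e-9)
  }
})

test_that("the LU significance map flags group differences", {
  mk_tab <- function(sizes_a, sizes_b, L = 0.5, U = 0.7) {
    n <- length(sizes_a)
    data.frame(patient = c(paste0("a", seq_len(n)), paste0("b", seq_len(n))),
               group = rep(c("A", "B"), each = n),
               L = L, U = U, relative_size = c(sizes_a, sizes_b))
  }
  # identical groups: p = 1 everywhere, empty significance mask
  t_same <- mk_tab(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  r_same <- lu_significance_map(t_same, alpha = 0.05)
  expect_equal(r_same$p_value, 1)
  expect_false(any(r_same$significant))

  # disjoint supports: p is the exact minimum for 3 vs 3 (2 / C(6,3) = 0.1)
  t_disj <- mk_tab(c(0.1, 0.12, 0.11), c(0.4, 0.42, 0.41))
  r_disj <- lu_significance_map(t_disj, alpha = 0.2)
  expect_equal(r_disj$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r_disj$p_value,
               oracle_mann_whitney(c(0.1, 0.12, 0.11), c(0.4, 0.42, 0.41))$p_value)

  expect_error(lu_significance_map(mk_tab(0.1, 0.2)), "at least 2")
  # BH adjustment is available but off by default
  t2 <- rbind(mk_tab(c(0.1, 0.12, 0.11), c(0.4, 0.42, 0.41), L = 0, U = 0.5),
              mk_tab(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2), L = 0.5, U = 1))
  r_bh <- lu_significance_map(t2, alpha = 0.2, adjust = "BH")
  expect_equal(r_bh$p_value[1], 0.2)   # 0.1 * 2 / 1
})

test_that("intensity baseline segments follow the 3-D max-scar threshold rule", {
  sl <- generate_phantom(phantom_spec(seed = 33))
  segs <- intensity_baseline_segment(list(sl$image), list(sl$annotation), 0, 1)
  m <- max(sl$image[sl$annotation$scar])
  expect_identical(segs[[1]], sl$annotation$myocardium & sl$image <= m)

  # constant-intensity scar with L above its relative level: empty
  img <- matrix(0.2, 8, 8)
  myo <- matrix(TRUE, 8, 8)
  scar <- matrix(FALSE, 8, 8)
  scar[4:5, 4:5] <- TRUE
  img[scar] <- 0.5
  out <- intensity_baseline_segment(list(img), list(region_annotation(myo, scar)),
                                    L = 1.0 + 1e-9, U = 1)
  expect_equal(sum(out[[1]]), 0)

  # brute-force per-pixel oracle
  L <- 0.3
  U <- 0.8
  got <- intensity_baseline_segment(list(sl$image), list(sl$annotation), L, U)[[1]]
  for (probe in list(c(20, 20), c(32, 40), c(10, 32))) {
    i <- probe[1]; j <- probe[2]
    want <- sl$annotation$myocardium[i, j] &&
      sl$image[i, j] >= L * m && sl$image[i, j] < U * m
    expect_equal(got[i, j], want)
  }
  expect_error(intensity_baseline_segment(list(img),
                                          list(region_annotation(myo, myo & FALSE)),
                                          0, 1),
               "no scar")
})
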