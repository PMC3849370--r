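ann_of <- function(myo, scar) region_annotation(myo, scar)

test_that("the scar prior is the pooled pixel ratio", {
  mk <- function(n_myo, n_scar, shape = c(40, 40)) {
    myo <- matrix(FALSE, shape[1], shape[2])
    myo[seq_len(n_myo)] <- TRUE
    scar <- matrix(FALSE, shape[1], shape[2])
    scar[seq_len(n_scar)] <- TRUE
    ann_of(myo, scar)
  }
  expect_equal(estimate_prior(mk(1000, 200)), 0.2)
  expect_equal(estimate_prior(list(mk(400, 100), mk(600, 50))), 0.15)
  expect_error(estimate_prior(mk(500, 0)), "degenerate")
  expect_error(estimate_prior(mk(0, 0)), "no myocardium")
})

test_that("ML Gaussian fitting divides by n and standardizes on the pool", {
  m <- fit_class_model(c(0, 2), c(5, 7, 9), standardize = FALSE,
                       prior_scar = 0.3)
  expect_equal(m$scar_mean, 1)
  expect_equal(m$scar_sd, 1)         # ML: sqrt(((0-1)^2 + (2-1)^2)/2)

  # pooled values {0, 0, 2, 2}: scaler mean 1, ML sd 1
  ms <- fit_class_model(c(0, 2), c(0, 2), standardize = TRUE, prior_scar = 0.5)
  expect_equal(unname(ms$scaler["mean"]), 1)
  expect_equal(unname(ms$scaler["sd"]), 1)

  set.seed(18)
  draws <- stats::rnorm(1e5, mean = 3, sd = 2)
  mc <- fit_class_model(draws, stats::rnorm(1e4), standardize = FALSE,
                        prior_scar = 0.5)
  expect_lt(abs(mc$scar_mean - 3) / 3, 0.01)
  expect_lt(abs(mc$scar_sd - 2) / 2, 0.01)

  expect_error(fit_class_model(c(1, 1), c(0, 2), standardize = FALSE),
               "variance")
  expect_error(fit_class_model(1, c(0, 2)), "at least 2")
})

test_that("the posterior is the logistic of the log-odds and normalizes", {
  m <- fit_class_model(c(1 - 1e-8, 1 + 1e-8), c(-1 - 1e-8, -1 + 1e-8),
                       standardize = FALSE, prior_scar = 0.5)
  m$scar_sd <- 1
  m$myo_sd <- 1
  # scar N(1,1), myo N(-1,1), prior 1/2, v = 1: closed form 1/(1+e^-2)
  expect_equal(posterior(1, m), 1 / (1 + exp(-2)), tolerance = 1e-9)
  expect_equal(posterior(-1, m), 1 / (1 + exp(2)), tolerance = 1e-9)
  expect_equal(posterior(0, m), 0.5, tolerance = 1e-12)

  # P(scar|v) + P(myo|v) = 1: the complementary model swaps roles and prior
  m2 <- m
  m2$scar_mean <- m$myo_mean
  m2$myo_mean <- m$scar_mean
  grid <- seq(-50, 50, length.out = 1e4)
  expect_lt(max(abs(posterior(grid, m) + posterior(grid, m2) - 1)), 1e-12)

  # deep tails stay finite and on the correct side
  far <- posterior(-20, m)
  expect_true(is.finite(far) && far < 0.5)
  expect_true(is.na(posterior(NaN, m)))

  # equal sds and scar mean above myo mean: monotone non-decreasing in v
  expect_true(all(diff(posterior(seq(-30, 30, length.out = 2000), m)) >= 0))
})

test_that("probability maps evaluate the posterior on the myocardium only", {
  myo <- matrix(FALSE, 16, 16)
  myo[4:13, 4:13] <- TRUE
  scar <- matrix(FALSE, 16, 16)
  scar[6:9, 6:9] <- TRUE
  ann <- ann_of(myo, scar)
  m <- fit_class_model(c(0.8, 1.2), c(-1.2, -0.8), standardize = FALSE,
                       prior_scar = 0.5)

  # symmetric model, feature constant at the midpoint: uniform 0.5
  mid <- probability_map(matrix(0, 16, 16), ann, m)
  expect_true(all(abs(mid[myo] - 0.5) < 1e-12))
  expect_true(all(is.na(mid[!myo])))

  # each pixel equals the scalar posterior call
  set.seed(19)
  f <- matrix(stats::rnorm(256), 16, 16)
  pm <- probability_map(f, ann, m)
  for (px in list(c(4, 4), c(8, 9), c(13, 13))) {
    expect_equal(pm[px[1], px[2]], posterior(f[px[1], px[2]], m))
  }

  # the stored scaler is applied at prediction time
  msc <- fit_class_model(c(10, 12), c(2, 4), standardize = TRUE, prior_scar = 0.4)
  pms <- probability_map(f, ann, msc)
  v <- (f[5, 5] - msc$scaler[["mean"]]) / msc$scaler[["sd"]]
  expect_equal(pms[5, 5], posterior(v, msc))

  f_bad <- f
  f_bad[5, 5] <- NA
  expect_error(probability_map(f_bad, ann, m), "1 myocardium pixel")
})

test_that("a scar-free phantom maps to mostly low probabilities", {
  fit <- dc_fit()
  sp <- phantom_spec(scar_start_angle = 10, scar_end_angle = 10,
                     border_band_width = 0, seed = 77)
  sl <- generate_phantom(sp)
  map <- predict(fit, sl)[[1]]
  expect_lt(stats::median(map[!is.na(map)]), 0.5)
})

test_that("minimum-error segmentation thresholds at 1/2 with ties healthy", {
  m <- matrix(c(0.5, 1, 0.2, NA), 2, 2)
  class(m) <- c("probability_map", "matrix", "array")
  seg <- minimum_error_segmentation(m)
  expect_identical(as.vector(seg), c(FALSE, TRUE, FALSE, FALSE))

  set.seed(20)
  r <- matrix(stats::runif(100), 10, 10)
  class(r) <- c("probability_map", "matrix", "array")
  expect_identical(minimum_error_segmentation(r), unclass(r) > 0.5)
})

test_that("rendering hits the anchor colors and is a pure function", {
  m <- matrix(NA_real_, 3, 3)
  m[1, 1] <- 1
  m[2, 2] <- 0
  class(m) <- c("probability_map", "matrix", "array")
  rgb1 <- render_map(m)
  darkred <- as.numeric(grDevices::col2rgb("darkred")) / 255
  blue <- as.numeric(grDevices::col2rgb("blue")) / 255
  expect_equal(rgb1[1, 1, ], darkred)
  expect_equal(rgb1[2, 2, ], blue)
  # non-myocardium pixels are pink-tinted
  pink <- as.numeric(grDevices::col2rgb("lightpink")) / 255
  expect_equal(rgb1[3, 3, ], pink)
  expect_identical(rgb1, render_map(m))

  bg <- matrix(seq(0, 1, length.out = 9), 3, 3)
  rgb2 <- render_map(m, bg)
  expect_equal(rgb2[1, 1, ], darkred)   # map pixels ignore the background
})

test_that("class models round-trip through JSON", {
  m <- fit_class_model(c(0.8, 1.2, 0.9), c(-1.2, -0.8), standardize = TRUE,
                       prior_scar = 0.25, feature_name = "dc")
  f <- withr::local_tempfile(fileext = ".json")
  write_class_model(m, f)
  back <- read_class_model(f)
  expect_equal(back$scar_mean, m$scar_mean)
  expect_equal(back$scaler[["mean"]], m$scaler[["mean"]])
  expect_equal(posterior(0.3, back), posterior(0.3, m))
})
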