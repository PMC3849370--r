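# The dictionary-based texture feature: per-pixel ORMP representation
# residuals against the scar and healthy dictionaries, Gaussian smoothing of
# the two residual images, and the residual-ratio feature
# R_p = R_m / (R_s + R_m) in [0, 1] (high = the scar dictionary explains the
# patch better, i.e. scar-like texture).

#' Per-pixel representation residuals against two class dictionaries
#'
#' For every pixel whose full `n` x `n` window lies inside the image, the
#' vectorized patch (mean-subtracted iff `remove_dc`) is ORMP-coded against
#' both dictionaries at the given sparsity; the two residual norms form the
#' residual images `R_s` (scar dictionary) and `R_m` (healthy dictionary).
#' Residuals are computed over the whole valid field, not only the
#' myocardium, so later smoothing needs no mask-boundary renormalization.
#'
#' @param image numeric matrix.
#' @param d_s,d_m scar and healthy [texture_dictionary()]s with atom length
#'   `n^2`.
#' @param n odd patch size.
#' @param sparsity ORMP sparsity (default 2).
#' @param remove_dc subtract each patch's mean before coding?  Must match how
#'   the dictionaries were trained.
#' @return An object of class `"residual_pair"`: list with numeric matrices
#'   `r_s` and `r_m` (`NA` on the margin where the window does not fit).
#' @export
residual_images <- function(image, d_s, d_m, n = 3L, sparsity = 2L,
                            remove_dc = FALSE) {
  n <- stopifnot_odd(n, "patch size")
  for (d in list(d_s, d_m))
    if (nrow(d) != n * n)
      stop("dictionary atom length ", nrow(d), " does not match ", n, "x", n,
           " patches")
  for (d in list(d_s, d_m))
    if (!is.null(attr(d, "remove_dc")) &&
        !identical(isTRUE(attr(d, "remove_dc")), isTRUE(remove_dc)))
      warning("remove_dc flag differs from the dictionary's training flag")
  patches <- extract_patches(image, n)
  x <- patches$x
  if (remove_dc) x <- sweep(x, 2L, colMeans(x))
  r_s <- matrix(NA_real_, nrow(image), ncol(image))
  r_m <- r_s
  r_s[patches$centers] <- ormp_residual_norms(d_s, x, sparsity)
  r_m[patches$centers] <- ormp_residual_norms(d_m, x, sparsity)
  structure(list(r_s = r_s, r_m = r_m), class = "residual_pair")
}

gaussian_kernel_1d <- function(window, sigma) {
  h <- (window - 1L) %/% 2L
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable convolution with replicate edges along one dimension.
smooth_1d <- function(m, g, along_rows) {
  h <- (length(g) - 1L) %/% 2L
  n <- if (along_rows) nrow(m) else ncol(m)
  out <- 0 * m
  for (k in seq_along(g)) {
    idx <- pmin(pmax(seq_len(n) + (k - 1L - h), 1L), n)
    out <- out + g[k] * (if (along_rows) m[idx, , drop = FALSE]
                         else m[, idx, drop = FALSE])
  }
  out
}

#' Separable Gaussian smoothing
#'
#' Convolution with a normalized `window` x `window` separable Gaussian kernel
#' of standard deviation `sigma`, with replicate-edge handling.  A constant
#' image is unchanged; `window = 1` is the identity.  Texture is not a
#' pixel-local property, so the residual images are smoothed this way before
#' forming the residual ratio.
#'
#' If the image carries an `NA` margin (as residual images do), the smoothing
#' runs on the bounding box of the finite values and the margin is preserved.
#'
#' @param image numeric matrix, possibly with a rectangular `NA` margin.
#' @param window odd kernel size (default 9).
#' @param sigma Gaussian standard deviation in pixels (default 5).
#' @return A numeric matrix of the same shape.
#' @export
smooth_image <- function(image, window = 9L, sigma = 5) {
  window <- stopifnot_odd(window, "smoothing window")
  if (sigma <= 0) stop("sigma must be > 0")
  if (anyNA(image)) {
    ok <- which(is.finite(image), arr.ind = TRUE)
    if (!nrow(ok)) return(image)
    rr <- range(ok[, 1])
    cc <- range(ok[, 2])
    sub <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    if (anyNA(sub)) stop("NA values inside the image interior")
    out <- image
    out[rr[1]:rr[2], cc[1]:cc[2]] <- smooth_image(sub, window, sigma)
    return(out)
  }
  g <- gaussian_kernel_1d(window, sigma)
  smooth_1d(smooth_1d(image, g, along_rows = TRUE), g, along_rows = FALSE)
}

#' Residual-ratio texture feature image
#'
#' `R_p = R_m / (R_s + R_m)` pointwise, in `[0, 1]`: values near 1 mean the
#' scar dictionary represents the local texture much better than the healthy
#' dictionary.  Pixels where both residuals are exactly 0 (both dictionaries
#' represent the patch perfectly) are set to the non-informative value 0.5.
#'
#' @param residuals a [residual_images()] pair (typically smoothed first; the
#'   smoothing happens on the residual images, never on the ratio).
#' @return A numeric matrix in `[0, 1]` (`NA` where the residuals are
#'   undefined).
#' @export
rp_image <- function(residuals) {
  r_s <- residuals$r_s
  r_m <- residuals$r_m
  if (any(r_s < 0, na.rm = TRUE) || any(r_m < 0, na.rm = TRUE))
    stop("residual images must be nonnegative")
  tot <- r_s + r_m
  out <- r_m / tot
  out[!is.na(tot) & tot == 0] <- 0.5
  out
}
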