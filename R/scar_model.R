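# The user-facing fitted-model surface: scar_model() trains the whole
# probability-mapping pipeline on annotated training slices (prior, feature
# extraction, optional dictionary learning, ML Gaussian fit) and predict()
# turns new slices into probability maps.

#' Fit a myocardial scar probability-mapping model
#'
#' Trains everything Bayes rule needs from a set of annotated training slices:
#' the scar prior (pooled scar/myocardium pixel ratio), the per-pixel feature
#' (local-mean `"dc"` or dictionary-based `"texture"`), and the
#' class-conditional Gaussian densities fitted by maximum likelihood.
#'
#' For the `"texture"` feature, class-pure patch vectors are collected with
#' the boundary-exclusion rule ([collect_training_vectors()]), a scar and a
#' healthy dictionary are learned with RLS-DLA, and the training feature is
#' the raw (unsmoothed) residual ratio `R_p`; at prediction time the residual
#' images are Gaussian-smoothed before the ratio, since texture is not a
#' pixel-local property.  Set `smooth_training = TRUE` to smooth the training
#' residual images as well.
#'
#' DC features are standardized to zero mean / unit variance (pooled over both
#' classes) before the ML fit by default; texture features (already confined
#' to `[0, 1]`) are not.  Override with `standardize`.
#'
#' @param slices a list of training slices, each a list with elements `image`
#'   (numeric matrix) and `annotation` (a [region_annotation()]); a
#'   `phantom_slice` works directly.
#' @param feature `"dc"` or `"texture"`.
#' @param patch odd neighborhood size N (default 3).
#' @param atoms dictionary size K (texture only, default 90).
#' @param sparsity ORMP sparsity s (texture only, default 2).
#' @param lambda0 initial RLS-DLA forgetting factor (default 0.995).
#' @param epochs dictionary-learning passes (default 40).
#' @param smooth_window,smooth_sigma Gaussian smoothing of the test residual
#'   images (defaults 9 and 5).
#' @param remove_dc learn dictionaries on mean-subtracted patches?
#' @param standardize override the feature-standardization default.
#' @param smooth_training smooth training residual images too (default FALSE).
#' @param seed integer seed governing dictionary initialization/shuffling.
#' @return An object of class `"scar_model"` with `print()`, `summary()`,
#'   `coef()`, `predict()` and `plot()` methods.
#' @examples
#' train <- lapply(1:2, function(i) generate_phantom(phantom_spec(seed = i)))
#' fit <- scar_model(train, feature = "dc")
#' test <- generate_phantom(phantom_spec(seed = 99))
#' map <- predict(fit, test)[[1]]
#' range(map, na.rm = TRUE)
#' @export
scar_model <- function(slices, feature = c("dc", "texture"), patch = 3L,
                       atoms = 90L, sparsity = 2L, lambda0 = 0.995,
                       epochs = 40L, smooth_window = 9L, smooth_sigma = 5,
                       remove_dc = FALSE, standardize = NULL,
                       smooth_training = FALSE, seed = 1L) {
  feature <- match.arg(feature)
  slices <- as_slice_list(slices)
  slices <- lapply(slices, function(sl) {
    sl$annotation <- validate_annotation(sl$annotation, sl$image)
    sl
  })
  prior <- estimate_prior(lapply(slices, `[[`, "annotation"))
  if (is.null(standardize)) standardize <- feature == "dc"

  dictionaries <- NULL
  if (feature == "dc") {
    feats <- lapply(slices, function(sl) dc_image(sl$image, patch))
  } else {
    sets <- lapply(seq_along(slices), function(i)
      collect_training_vectors(slices[[i]]$image, slices[[i]]$annotation,
                               n = patch, remove_dc = remove_dc,
                               slice_id = sprintf("train_%02d", i)))
    scar_set <- merge_training_sets(lapply(sets, `[[`, "scar"))
    myo_set <- merge_training_sets(lapply(sets, `[[`, "myo"))
    dictionaries <- list(
      scar = train_dictionary(scar_set, K = atoms, sparsity = sparsity,
                              epochs = epochs, lambda0 = lambda0,
                              seed = derive_seed(seed, 1L),
                              class_role = "scar", remove_dc = remove_dc),
      myo = train_dictionary(myo_set, K = atoms, sparsity = sparsity,
                             epochs = epochs, lambda0 = lambda0,
                             seed = derive_seed(seed, 2L),
                             class_role = "myo", remove_dc = remove_dc))
    feats <- lapply(slices, function(sl) {
      res <- residual_images(sl$image, dictionaries$scar, dictionaries$myo,
                             n = patch, sparsity = sparsity,
                             remove_dc = remove_dc)
      if (smooth_training) {
        res$r_s <- smooth_image(res$r_s, smooth_window, smooth_sigma)
        res$r_m <- smooth_image(res$r_m, smooth_window, smooth_sigma)
      }
      rp_image(res)
    })
  }

  scar_vals <- unlist(lapply(seq_along(slices), function(i) {
    f <- feats[[i]]
    f[slices[[i]]$annotation$scar]
  }))
  myo_vals <- unlist(lapply(seq_along(slices), function(i) {
    f <- feats[[i]]
    a <- slices[[i]]$annotation
    f[a$myocardium & !a$scar]
  }))
  scar_vals <- scar_vals[is.finite(scar_vals)]
  myo_vals <- myo_vals[is.finite(myo_vals)]
  if (feature == "texture") {
    # keep the Gaussian fit away from the degenerate endpoints of [0, 1]
    scar_vals <- pmin(pmax(scar_vals, 1e-9), 1 - 1e-9)
    myo_vals <- pmin(pmax(myo_vals, 1e-9), 1 - 1e-9)
  }
  model <- fit_class_model(scar_vals, myo_vals, standardize = standardize,
                           prior_scar = prior, feature_name = feature)

  structure(list(feature = feature, model = model, dictionaries = dictionaries,
                 patch = as.integer(patch), sparsity = as.integer(sparsity),
                 atoms = as.integer(atoms), lambda0 = lambda0,
                 epochs = as.integer(epochs),
                 smooth_window = as.integer(smooth_window),
                 smooth_sigma = smooth_sigma, remove_dc = remove_dc,
                 smooth_training = smooth_training, seed = as.integer(seed),
                 n_train_slices = length(slices), call = match.call()),
            class = "scar_model")
}

# Accept a single slice, a phantom_slice, or a list of slices.
as_slice_list <- function(x) {
  if (!is.null(x$image)) x <- list(x)
  lapply(x, function(sl) {
    if (is.null(sl$image) || is.null(sl$annotation))
      stop("each slice needs elements 'image' and 'annotation'")
    sl
  })
}

#' Compute the feature image of a slice under a fitted model
#'
#' DC: the sliding-mean image.  Texture: ORMP residual images against the two
#' learned dictionaries, Gaussian-smoothed, then the residual ratio `R_p`.
#'
#' @param object a [scar_model()].
#' @param slice a list with `image` (and optionally `annotation`).
#' @return A numeric matrix of feature values (`NA` margin).
#' @export
feature_image <- function(object, slice) {
  stopifnot(inherits(object, "scar_model"))
  if (object$feature == "dc") {
    dc_image(slice$image, object$patch)
  } else {
    res <- residual_images(slice$image, object$dictionaries$scar,
                           object$dictionaries$myo, n = object$patch,
                           sparsity = object$sparsity,
                           remove_dc = object$remove_dc)
    res$r_s <- smooth_image(res$r_s, object$smooth_window, object$smooth_sigma)
    res$r_m <- smooth_image(res$r_m, object$smooth_window, object$smooth_sigma)
    rp_image(res)
  }
}

#' Predict probability maps for new slices
#'
#' @param object a [scar_model()].
#' @param newdata a slice or list of slices (each with `image` and
#'   `annotation`).
#' @param type `"map"` (posterior probability maps), `"feature"` (feature
#'   images) or `"segmentation"` (minimum-error scar masks).
#' @param ... unused.
#' @return A list with one element per slice: [probability_map()]s, feature
#'   matrices, or logical masks according to `type`.
#' @export
predict.scar_model <- function(object, newdata,
                               type = c("map", "feature", "segmentation"), ...) {
  type <- match.arg(type)
  slices <- as_slice_list(newdata)
  lapply(slices, function(sl) {
    f <- feature_image(object, sl)
    if (type == "feature") return(f)
    m <- probability_map(f, sl$annotation, object$model)
    if (type == "map") m else minimum_error_segmentation(m)
  })
}

#' @export
print.scar_model <- function(x, ...) {
  cat("Myocardial scar probability-mapping model\n")
  cat(sprintf("  feature: %s (patch %dx%d)\n", x$feature, x$patch, x$patch))
  if (x$feature == "texture")
    cat(sprintf("  dictionaries: %d x %d atoms, sparsity %d, lambda0 %.4g, %d epochs%s\n",
                x$patch^2, x$atoms, x$sparsity, x$lambda0, x$epochs,
                if (x$remove_dc) ", DC removed" else ""))
  cat(sprintf("  trained on %d slice(s); prior P(scar) = %.4f\n",
              x$n_train_slices, x$model$prior_scar))
  invisible(x)
}

#' @export
summary.scar_model <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$model)
  if (object$feature == "texture") {
    cat(sprintf("\n  smoothing: %dx%d Gaussian, sigma = %.3g (test residual images)\n",
                object$smooth_window, object$smooth_window, object$smooth_sigma))
    cat(sprintf("  atom derivative statistic: scar %.4f, myo %.4f\n",
                atom_derivative_statistic(object$dictionaries$scar),
                atom_derivative_statistic(object$dictionaries$myo)))
  }
  invisible(object)
}

#' @export
coef.scar_model <- function(object, ...) {
  m <- object$model
  c(prior_scar = m$prior_scar, scar_mean = m$scar_mean, scar_sd = m$scar_sd,
    myo_mean = m$myo_mean, myo_sd = m$myo_sd)
}

#' Plot the fitted class-conditional densities and posterior
#'
#' Base-graphics view of the two Gaussian class densities (on the fitted
#' feature scale) with the posterior probability curve overlaid.
#'
#' @param x a [scar_model()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.scar_model <- function(x, ...) {
  m <- x$model
  lo <- min(m$scar_mean - 4 * m$scar_sd, m$myo_mean - 4 * m$myo_sd)
  hi <- max(m$scar_mean + 4 * m$scar_sd, m$myo_mean + 4 * m$myo_sd)
  v <- seq(lo, hi, length.out = 400)
  ds <- stats::dnorm(v, m$scar_mean, m$scar_sd)
  dm <- stats::dnorm(v, m$myo_mean, m$myo_sd)
  graphics::plot(v, ds, type = "l", col = "firebrick", lwd = 2,
                 xlab = sprintf("%s feature%s", m$feature_name,
                                if (!is.null(m$scaler)) " (standardized)" else ""),
                 ylab = "density", ylim = c(0, max(ds, dm)), ...)
  graphics::lines(v, dm, col = "steelblue", lwd = 2)
  graphics::par(new = TRUE)
  graphics::plot(v, posterior(v, m), type = "l", lty = 2, axes = FALSE,
                 xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("P(scar | v)", side = 4, line = 2)
  graphics::legend("topleft", c("scar", "myo", "posterior"),
                   col = c("firebrick", "steelblue", "black"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}
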