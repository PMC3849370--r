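# Bayes posterior probability maps.  Class-conditional feature densities
# p(v | scar) and p(v | myo) are univariate Gaussians fitted by maximum
# likelihood on labeled training features; the prior P(scar) is the pooled
# scar/myocardium pixel ratio of the training slices; the map assigns every
# myocardial pixel its posterior
#   P(scar | v) = P(scar) p(v|scar) / [P(scar) p(v|scar) + P(myo) p(v|myo)],
# computed in the log domain for tail stability.

#' Scar prior from training annotations
#'
#' The pooled ratio of scar pixels to myocardium pixels over all training
#' slices — the mean relative scar size of the training data.
#'
#' @param annotations a list of [region_annotation()]s (or a single one).
#' @return The prior probability `P(scar)` in `(0, 1)`.
#' @export
estimate_prior <- function(annotations) {
  if (inherits(annotations, "region_annotation")) annotations <- list(annotations)
  n_scar <- sum(vapply(annotations, function(a) sum(a$scar), 0))
  n_myo <- sum(vapply(annotations, function(a) sum(a$myocardium), 0))
  if (n_myo == 0) stop("no myocardium pixels in the training annotations")
  p <- n_scar / n_myo
  if (p <= 0 || p >= 1)
    stop(sprintf("degenerate scar prior %.3f: training data must contain both classes", p))
  p
}

#' Fit the class-conditional Gaussian model
#'
#' Maximum-likelihood Gaussian estimates per class: mean = sample mean,
#' sd = sqrt(mean squared deviation) (divisor `n`, not `n - 1`).  With
#' `standardize = TRUE` a scaler (mean/sd of the pooled training values of
#' both classes) is fitted first, applied before the ML estimates, and stored
#' for test-time reuse.
#'
#' @param scar_features,myo_features numeric vectors of training feature
#'   values (>= 2 each).
#' @param standardize scale the pooled features to zero mean / unit variance?
#' @param prior_scar the scar prior, from [estimate_prior()].
#' @param feature_name `"dc"` or `"texture"` (metadata).
#' @return An object of class `"class_probability_model"`: list with
#'   `scar_mean`, `scar_sd`, `myo_mean`, `myo_sd`, `scaler` (NULL or
#'   `c(mean, sd)`), `prior_scar`, `feature_name`.
#' @export
fit_class_model <- function(scar_features, myo_features, standardize = TRUE,
                            prior_scar = 0.5, feature_name = "feature") {
  scar_features <- scar_features[is.finite(scar_features)]
  myo_features <- myo_features[is.finite(myo_features)]
  if (length(scar_features) < 2 || length(myo_features) < 2)
    stop("each class needs at least 2 finite training feature values")
  if (prior_scar <= 0 || prior_scar >= 1) stop("prior_scar must lie in (0, 1)")
  scaler <- NULL
  if (standardize) {
    pooled <- c(scar_features, myo_features)
    scaler <- c(mean = mean(pooled),
                sd = sqrt(mean((pooled - mean(pooled))^2)))   # ML, divisor n
    if (scaler[["sd"]] == 0) stop("pooled training features are constant")
    scar_features <- (scar_features - scaler[["mean"]]) / scaler[["sd"]]
    myo_features <- (myo_features - scaler[["mean"]]) / scaler[["sd"]]
  }
  ml <- function(x) {
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s == 0)
      stop("zero within-class variance; inspect the feature values")
    c(m, s)
  }
  s_par <- ml(scar_features)
  m_par <- ml(myo_features)
  structure(list(scar_mean = s_par[1], scar_sd = s_par[2],
                 myo_mean = m_par[1], myo_sd = m_par[2],
                 scaler = scaler, prior_scar = prior_scar,
                 feature_name = feature_name,
                 n_scar = length(scar_features), n_myo = length(myo_features)),
            class = "class_probability_model")
}

#' @export
print.class_probability_model <- function(x, ...) {
  cat(sprintf("class-conditional Gaussian model (feature '%s')\n", x$feature_name))
  cat(sprintf("  scar: N(%.4g, %.4g^2)  [n = %d]\n", x$scar_mean, x$scar_sd, x$n_scar))
  cat(sprintf("  myo : N(%.4g, %.4g^2)  [n = %d]\n", x$myo_mean, x$myo_sd, x$n_myo))
  cat(sprintf("  prior P(scar) = %.4g%s\n", x$prior_scar,
              if (!is.null(x$scaler)) "  (standardized features)" else ""))
  invisible(x)
}

#' Posterior probability of scar for a feature value
#'
#' Bayes rule with Gaussian class-conditional densities, evaluated in the log
#' domain (the posterior is the logistic of the log-odds), so values deep in
#' both tails stay finite.  The feature value is assumed to be on the scale
#' the model was fitted on; [probability_map()] applies the stored scaler
#' before calling this.
#'
#' @param feature_value numeric vector of feature values.
#' @param model a [fit_class_model()].
#' @return Posterior probabilities `P(scar | v)` in `[0, 1]` (`NA` for
#'   non-finite input).
#' @export
posterior <- function(feature_value, model) {
  stopifnot(inherits(model, "class_probability_model"))
  out <- rep(NA_real_, length(feature_value))
  ok <- is.finite(feature_value)
  v <- feature_value[ok]
  log_odds <- log(model$prior_scar) - log1p(-model$prior_scar) +
    stats::dnorm(v, model$scar_mean, model$scar_sd, log = TRUE) -
    stats::dnorm(v, model$myo_mean, model$myo_sd, log = TRUE)
  out[ok] <- stats::plogis(log_odds)
  out
}

#' Per-pixel probability map of the myocardium
#'
#' Evaluates the posterior at every myocardium pixel of a feature image
#' (applying the model's stored scaler first, when present); non-myocardium
#' pixels are `NA`.
#'
#' @param feature_image numeric matrix of feature values (e.g. [dc_image()]
#'   or [rp_image()]); must be defined on all myocardium pixels.
#' @param annotation a [region_annotation()].
#' @param model a [fit_class_model()].
#' @return An object of class `"probability_map"`: a numeric matrix with
#'   posterior values on the myocardium and `NA` elsewhere; the feature name
#'   is stored as attribute `feature_name`.
#' @export
probability_map <- function(feature_image, annotation, model) {
  stopifnot(inherits(annotation, "region_annotation"),
            inherits(model, "class_probability_model"))
  if (!identical(dim(feature_image), dim(annotation$myocardium)))
    stop("feature image and annotation shapes differ")
  myo <- annotation$myocardium
  v <- feature_image[myo]
  n_bad <- sum(!is.finite(v))
  if (n_bad > 0)
    stop(n_bad, " myocardium pixel(s) have undefined feature values")
  if (!is.null(model$scaler))
    v <- (v - model$scaler[["mean"]]) / model$scaler[["sd"]]
  out <- matrix(NA_real_, nrow(feature_image), ncol(feature_image))
  out[myo] <- posterior(v, model)
  structure(out, class = c("probability_map", "matrix", "array"),
            feature_name = model$feature_name)
}

#' Minimum-error segmentation of a probability map
#'
#' Classifies a pixel as scar iff `P(scar | v) > 0.5` (i.e.
#' `P(scar|v) > P(myo|v)`); exact ties go to healthy.
#'
#' @param map a [probability_map()].
#' @return A logical matrix (FALSE outside the myocardium).
#' @export
minimum_error_segmentation <- function(map) {
  out <- !is.na(map) & unclass(map) > 0.5
  dim(out) <- dim(map)
  out
}

# Color-code anchors: probability 1 renders dark red, 0 renders blue, with
# red / yellow / green / cyan in between; piecewise-linear interpolation.
map_color_anchors <- function() {
  cols <- t(grDevices::col2rgb(c("blue", "cyan", "green", "yellow", "red", "darkred"))) / 255
  list(p = c(0, 0.40, 0.55, 0.65, 0.85, 1), rgb = cols)
}

#' Render a probability map with the probability color code
#'
#' Probabilities are mapped through a continuous colormap interpolated
#' between the anchors blue (0) - cyan - green - yellow - red - dark red (1);
#' non-myocardium pixels are rendered as a light-pink tint of the grayscale
#' background image.  The rendering is a pure function of its inputs.
#'
#' @param map a [probability_map()].
#' @param background_image optional numeric matrix (scaled to `[0, 1]` for
#'   display); when `NULL` the background is plain light pink.
#' @return An `nrow x ncol x 3` RGB array in `[0, 1]`.
#' @export
render_map <- function(map, background_image = NULL) {
  anchors <- map_color_anchors()
  nr <- nrow(map)
  nc <- ncol(map)
  pink <- as.numeric(grDevices::col2rgb("lightpink")) / 255
  if (is.null(background_image)) {
    bg <- matrix(1, nr, nc)
  } else {
    rng <- range(background_image, finite = TRUE)
    bg <- if (diff(rng) > 0) (background_image - rng[1]) / diff(rng) else
      background_image * 0 + 0.5
  }
  out <- array(0, c(nr, nc, 3))
  defined <- !is.na(map)
  p <- pmin(pmax(unclass(map)[defined], 0), 1)
  for (ch in 1:3) {
    plane <- bg * pink[ch]              # light-pink tint over the background
    plane[defined] <- stats::approx(anchors$p, anchors$rgb[, ch], xout = p,
                                    rule = 2)$y
    out[, , ch] <- plane
  }
  out
}

#' Serialize / restore a class probability model as JSON
#'
#' @param model a [fit_class_model()].
#' @param path JSON file path.
#' @export
write_class_model <- function(model, path) {
  obj <- unclass(model)
  obj$scaler <- if (is.null(obj$scaler)) NULL else as.list(obj$scaler)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_class_model
#' @export
read_class_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$scaler)) obj$scaler <- unlist(obj$scaler)
  structure(obj, class = "class_probability_model")
}
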