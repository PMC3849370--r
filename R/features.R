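# Patch extraction, the local-mean (DC) feature image, and training-vector
# collection with the pure-neighborhood exclusion rule: a pixel contributes a
# training vector to a class only when its entire N x N neighborhood lies
# inside that class's region, so windows straddling a texture boundary (or the
# image edge) never contaminate the training sets.

#' Sliding local-mean (DC) feature image
#'
#' The DC value of a pixel is the arithmetic mean of the `n` x `n` window
#' centered on it ("DC" is the electronics name for the mean).  Because late
#' gadolinium enhancement makes scar hyperintense, this feature tracks the
#' intensity contrast a cardiologist uses when segmenting manually.
#'
#' The window is computed over the whole image; pixels whose full window does
#' not fit inside the image are returned as `NA`.
#'
#' @param image numeric matrix.
#' @param n odd window size (default 3).
#' @return A numeric matrix of the same shape, `NA` on the margin.
#' @export
dc_image <- function(image, n = 3L) {
  n <- stopifnot_odd(n, "neighborhood size")
  if (nrow(image) <= n || ncol(image) <= n)
    stop("image must be larger than the ", n, "x", n, " window")
  off <- window_offsets(n)
  acc <- matrix(0, nrow(image), ncol(image))
  for (k in seq_along(off$di))
    acc <- acc + shift_matrix(image, off$di[k], off$dj[k], fill = NA)
  acc / (n * n)
}

# All full-window patches of an image, vectorized in row-major window order.
# Returns list(x = N^2 x M matrix, centers = M x 2, index = logical matrix of
# valid centers).  Column m of x is the patch around centers[m, ].
extract_patches <- function(image, n = 3L) {
  n <- stopifnot_odd(n, "neighborhood size")
  h <- (n - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr < n || nc < n) stop("image smaller than the patch window")
  rows <- (1L + h):(nr - h)
  cols <- (1L + h):(nc - h)
  off <- window_offsets(n)
  m <- length(rows) * length(cols)
  x <- matrix(0, n * n, m)
  for (k in seq_along(off$di))
    x[k, ] <- as.vector(image[rows + off$di[k], cols + off$dj[k], drop = FALSE])
  centers <- cbind(row = rep(rows, times = length(cols)),
                   col = rep(cols, each = length(rows)))
  valid <- matrix(FALSE, nr, nc)
  valid[rows, cols] <- TRUE
  list(x = x, centers = centers, valid = valid, n = n)
}

# Erode a mask by the n x n box: TRUE where the whole window is inside `mask`.
erode_box <- function(mask, n) {
  off <- window_offsets(n)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_along(off$di))
    out <- out & shift_matrix(mask, off$di[k], off$dj[k], fill = FALSE)
  out
}

#' Collect class-pure training vectors from an annotated slice
#'
#' For every myocardium pixel the `n` x `n` patch is vectorized in fixed
#' row-major order.  The vector joins the scar training set iff all its pixels
#' are scar, and the healthy set iff all are healthy myocardium
#' (myocardium minus scar); windows that cross any region boundary or the
#' image edge contribute nothing.  With `remove_dc = TRUE` the patch mean is
#' subtracted from each vector, leaving only the textural variation.
#'
#' @param image numeric matrix.
#' @param annotation a validated [region_annotation()].
#' @param n odd neighborhood size.
#' @param remove_dc subtract the patch mean from each vector?
#' @param slice_id identifier stored in the provenance table.
#' @return A list with elements `scar` and `myo`, each of class
#'   `"training_set"`: a list with `class_label`, `vectors` (an `n^2` x L
#'   matrix, one vector per column) and `provenance` (slice id and center
#'   pixel per vector).
#' @export
collect_training_vectors <- function(image, annotation, n = 3L,
                                     remove_dc = FALSE, slice_id = "slice") {
  stopifnot(inherits(annotation, "region_annotation"))
  if (!identical(dim(image), dim(annotation$myocardium)))
    stop("image and annotation shapes differ")
  patches <- extract_patches(image, n)
  healthy <- annotation$myocardium & !annotation$scar
  pure <- list(scar = erode_box(annotation$scar, patches$n),
               myo = erode_box(healthy, patches$n))
  out <- lapply(names(pure), function(cls) {
    sel <- pure[[cls]][patches$centers]
    if (!any(sel))
      stop("no eligible training vectors for class '", cls,
           "': every candidate window crosses a region boundary")
    v <- patches$x[, sel, drop = FALSE]
    if (remove_dc) v <- sweep(v, 2L, colMeans(v))
    structure(list(class_label = cls, vectors = v,
                   provenance = data.frame(slice = slice_id,
                                           row = patches$centers[sel, 1],
                                           col = patches$centers[sel, 2])),
              class = "training_set")
  })
  names(out) <- names(pure)
  out
}

#' Merge training sets of the same class
#'
#' @param ... `"training_set"` objects with matching class labels and patch
#'   dimension.
#' @return A single merged `"training_set"`.
#' @export
merge_training_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "training_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  lab <- unique(vapply(sets, `[[`, "", "class_label"))
  if (length(lab) != 1) stop("cannot merge training sets of different classes")
  structure(list(class_label = lab,
                 vectors = do.call(cbind, lapply(sets, `[[`, "vectors")),
                 provenance = do.call(rbind, lapply(sets, `[[`, "provenance"))),
            class = "training_set")
}

#' Export a training set as delimited text
#'
#' One vector per line, tab-separated, for cross-tool inspection.
#'
#' @param set a `"training_set"`.
#' @param path output file.
#' @export
write_training_set <- function(set, path) {
  utils::write.table(t(set$vectors), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
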