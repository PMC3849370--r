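# Rasters, region annotations, and contour-to-mask conversion.
#
# Images are plain numeric matrices indexed (row, col); pixel centers sit at
# integer coordinates.  Manual segmentations arrive either as label masks or
# as closed contours of control points (the cardiologist's marked coordinates)
# which are interpolated with a periodic cubic spline and rasterized.

#' Region annotation for one slice
#'
#' Bundles the myocardium and scar masks of a slice.  The scar is expected to
#' be nested inside the myocardium; use [validate_annotation()] to enforce it.
#'
#' @param myocardium,scar logical matrices of identical shape.
#' @param source how the masks were obtained: `"mask_file"` or
#'   `"contour_points"`.
#' @return An object of class `"region_annotation"`.
#' @export
region_annotation <- function(myocardium, scar,
                              source = c("mask_file", "contour_points")) {
  source <- match.arg(source)
  if (!is_binary_mask(myocardium) || !is_binary_mask(scar))
    stop("masks must be binary matrices")
  if (!identical(dim(myocardium), dim(scar)))
    stop("myocardium and scar masks must have the same shape")
  structure(list(myocardium = as_mask(myocardium), scar = as_mask(scar),
                 source = source),
            class = "region_annotation")
}

#' Closed periodic cubic spline through contour control points
#'
#' Interpolates an ordered list of manually marked `(row, col)` control points
#' with a periodic cubic spline (uniform parameterization, one unit per
#' control point) and returns a closed polyline that passes through every
#' control point.
#'
#' Duplicate consecutive control points (including a repeated first point at
#' the end) are collapsed with a warning.
#'
#' @param control_points numeric matrix with columns `(row, col)`, at least 3
#'   distinct points.
#' @param samples number of polyline vertices to return.
#' @return A `samples` x 2 matrix of `(row, col)` vertices; the curve closes
#'   by wrap-around (last vertex connects to the first).
#' @export
spline_contour <- function(control_points, samples = 256L) {
  pts <- as.matrix(control_points)
  if (ncol(pts) != 2) stop("control_points must be an n x 2 (row, col) matrix")
  same <- rowSums(abs(pts - pts[c(nrow(pts), seq_len(nrow(pts) - 1L)), , drop = FALSE])) == 0
  same[1] <- nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ])
  if (any(same)) {
    warning("collapsing ", sum(same), " duplicate consecutive control point(s)")
    pts <- pts[!same, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 distinct control points")
  t_knots <- 0:n
  ts <- seq(0, n, length.out = samples + 1L)[-(samples + 1L)]
  fr <- stats::splinefun(t_knots, c(pts[, 1], pts[1, 1]), method = "periodic")
  fc <- stats::splinefun(t_knots, c(pts[, 2], pts[1, 2]), method = "periodic")
  cbind(row = fr(ts), col = fc(ts))
}

# TRUE where any two non-adjacent polyline edges properly intersect.
polyline_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    j <- j[!(i == 1L & j == n)]          # skip edges adjacent by wrap-around
    if (!length(j)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize a closed polyline into a binary mask
#'
#' Marks the pixels whose integer-coordinate centers lie strictly inside the
#' polygon, using the even-odd (crossing-number) rule, which is deterministic
#' and orientation-independent.  A self-intersecting contour triggers a
#' warning; the even-odd fill is still applied.
#'
#' @param polyline closed polyline as an n x 2 `(row, col)` matrix (last
#'   vertex connects back to the first).
#' @param shape integer length-2 raster shape `(rows, cols)`.
#' @return A logical matrix of the requested shape.
#' @export
rasterize_region <- function(polyline, shape) {
  poly <- as.matrix(polyline)
  stopifnot(ncol(poly) == 2, length(shape) == 2, all(shape >= 1))
  if (polyline_self_intersects(poly))
    warning("self-intersecting contour; even-odd fill applied")
  nr <- as.integer(shape[1])
  nc <- as.integer(shape[2])
  py <- poly[, 1]   # rows
  px <- poly[, 2]   # cols
  n <- nrow(poly)
  jnext <- c(2:n, 1)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  crossings <- matrix(0L, nr, nc)
  for (e in seq_len(n)) {
    y1 <- py[e]; y2 <- py[jnext[e]]
    x1 <- px[e]; x2 <- px[jnext[e]]
    if (y1 == y2) next
    # horizontal ray toward +col; half-open in row to count shared vertices once
    hit <- (rows >= pmin(y1, y2)) & (rows < pmax(y1, y2))
    xs <- x1 + (rows - y1) / (y2 - y1) * (x2 - x1)
    crossings <- crossings + as.integer(hit & xs > cols)
  }
  crossings %% 2L == 1L
}

#' Build a region annotation from closed contours
#'
#' Replicates the manual-segmentation workflow: spline-interpolate the outer
#' and inner myocardial contours and the scar contour, rasterize them, and
#' form `myocardium = inside(outer) & !inside(inner)` and
#' `scar = inside(scar contour) & myocardium`.
#'
#' @param outer,inner,scar control-point matrices (`(row, col)`, >= 3 points);
#'   `scar` may be `NULL` for a scar-free slice.
#' @param shape raster shape `(rows, cols)`.
#' @param samples spline samples per contour.
#' @return A [region_annotation()] with `source = "contour_points"`.
#' @export
annotation_from_contours <- function(outer, inner, scar = NULL, shape,
                                     samples = 256L) {
  myo <- rasterize_region(spline_contour(outer, samples), shape) &
    !rasterize_region(spline_contour(inner, samples), shape)
  sc <- if (is.null(scar)) matrix(FALSE, shape[1], shape[2]) else
    rasterize_region(spline_contour(scar, samples), shape) & myo
  region_annotation(myo, sc, source = "contour_points")
}

#' Validate an annotation against its image
#'
#' Checks shape agreement and the nesting `scar %subsetof% myocardium`.  When
#' at most 1% of scar pixels stray outside the myocardium they are clipped
#' with a warning (small contour-rasterization slack); a larger violation is
#' an error.
#'
#' @param annotation a [region_annotation()].
#' @param image the numeric matrix the annotation belongs to.
#' @return The (possibly clipped) annotation.
#' @export
validate_annotation <- function(annotation, image) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (!identical(dim(annotation$myocardium), dim(image)))
    stop("annotation shape does not match image shape")
  outside <- annotation$scar & !annotation$myocardium
  n_out <- sum(outside)
  if (n_out > 0) {
    n_scar <- sum(annotation$scar)
    if (n_out / n_scar <= 0.01) {
      warning(n_out, " scar pixel(s) outside the myocardium clipped")
      annotation$scar <- annotation$scar & annotation$myocardium
    } else {
      stop(sprintf("%d of %d scar pixels (%.1f%%) lie outside the myocardium",
                   n_out, n_scar, 100 * n_out / n_scar))
    }
  }
  annotation
}

#' Read and write grayscale images (PNG/TIFF)
#'
#' Thin wrappers over the \pkg{png} and \pkg{tiff} readers: images are
#' returned as numeric matrices in `[0, 1]`; multi-channel files are averaged
#' to grayscale.  `write_gray_image()` writes 32-bit (default) or 16-bit
#' integer-scaled TIFF of values in `[0, 1]` (values outside are clipped; at
#' 32 bits the quantization step is 2^-32, i.e. lossless for probability and
#' residual maps at double display precision).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_gray_image()`: a numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_gray_image
#' @param image numeric matrix.
#' @param bits bits per sample, 32 (default) or 16.
#' @export
write_gray_image <- function(image, path, bits = 32L) {
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = as.integer(bits),
                  reduce = FALSE)
  invisible(path)
}

#' Read and write label-mask PNGs
#'
#' Masks are stored as 8-bit label PNGs with 0 = background, 1 = myocardium,
#' 2 = scar (scar pixels are also myocardium).  The round trip is bit-exact.
#'
#' @param annotation a [region_annotation()].
#' @param path PNG file path.
#' @export
write_label_png <- function(annotation, path) {
  lab <- matrix(0L, nrow(annotation$myocardium), ncol(annotation$myocardium))
  lab[annotation$myocardium] <- 1L
  lab[annotation$scar] <- 2L
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  lab <- round(png::readPNG(path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  region_annotation(lab >= 1, lab == 2, source = "mask_file")
}

#' Read blank-line-separated contour CSV files
#'
#' Each contour is a block of `row,col` lines; blank lines separate contours.
#'
#' @param path file path.
#' @param offset constant added to all coordinates (use `offset = 1` for
#'   files written with 0-based indices).
#' @return A list of n x 2 matrices.
#' @export
read_contours <- function(path, offset = 0) {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- Filter(length, blocks)
  lapply(blocks, function(b) {
    m <- do.call(rbind, lapply(strsplit(b, ","), function(x) as.numeric(trimws(x))))
    colnames(m) <- c("row", "col")
    m + offset
  })
}
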