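# Synthetic textured cardiac phantoms: an annular "myocardium" containing an
# angular "scar" sector with its own mean intensity and spatial texture, and an
# optional blended gray-zone band at the scar edges.  Every downstream stage
# (features, dictionaries, probability maps, LU segments, ROC) is testable on
# these slices because the tissue labels are known by construction.

#' Specification of a synthetic cardiac phantom slice
#'
#' Describes the geometry, intensities, textures and noise of one synthetic
#' short-axis slice: an annulus (myocardium) between `inner_radius` and
#' `outer_radius`, containing an angular scar sector between
#' `scar_start_angle` and `scar_end_angle` (degrees, counterclockwise from the
#' positive x-axis).  The scar carries its own periodic texture and mean
#' intensity; a border band of width `border_band_width` pixels at the scar's
#' angular edges blends scar and healthy signal linearly, emulating the
#' peri-infarct gray zone where dead and viable fibers are interwoven.
#'
#' Both tissue textures are separable sinusoidal gratings
#' `A sin(2*pi*u/p) sin(2*pi*v/p)` in class-specific rotated coordinates
#' (healthy at 0 degrees, scar at 45 degrees), so that each class is a genuine
#' "tiled floor" texture that a small patch dictionary can represent sparsely.
#'
#' @param image_size side length of the square image, pixels.
#' @param center numeric length-2 `(row, col)` center; default image center.
#' @param inner_radius,outer_radius annulus radii, pixels;
#'   `0 < inner < outer < image_size/2`.
#' @param scar_start_angle,scar_end_angle scar sector limits in degrees; an
#'   extent of 0 means no scar.
#' @param border_band_width gray-zone thickness at the scar edge, pixels
#'   (arc length), `>= 0`.
#' @param healthy_mean,scar_mean tissue mean intensities.
#' @param texture_period_healthy,texture_period_scar grating periods, pixels.
#' @param texture_amplitude grating amplitude, intensity units.
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `"phantom_spec"` (a validated list).
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(image_size = 64,
                         center = NULL,
                         inner_radius = 10,
                         outer_radius = 22,
                         scar_start_angle = 30,
                         scar_end_angle = 150,
                         border_band_width = 3,
                         healthy_mean = 0.35,
                         scar_mean = 0.65,
                         texture_period_healthy = 4,
                         texture_period_scar = 7,
                         texture_amplitude = 0.12,
                         noise_sd = 0.02,
                         seed = 1L) {
  if (is.null(center)) center <- rep((image_size + 1) / 2, 2L)
  spec <- list(image_size = as.integer(image_size), center = as.numeric(center),
               inner_radius = inner_radius, outer_radius = outer_radius,
               scar_start_angle = scar_start_angle, scar_end_angle = scar_end_angle,
               border_band_width = border_band_width,
               healthy_mean = healthy_mean, scar_mean = scar_mean,
               texture_period_healthy = texture_period_healthy,
               texture_period_scar = texture_period_scar,
               texture_amplitude = texture_amplitude,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (!(inner_radius > 0 && inner_radius < outer_radius &&
        outer_radius < image_size / 2))
    stop("phantom geometry requires 0 < inner_radius < outer_radius < image_size/2")
  ext <- scar_extent_deg(spec)
  if (ext < 0 || ext > 360)
    stop("scar angular extent must lie in [0, 360] degrees")
  if (border_band_width < 0)
    stop("border_band_width must be >= 0")
  if (ext > 0) {
    # band cannot exceed half the sector's arc length at the inner radius,
    # nor the radial thickness of the annulus
    max_band <- min(inner_radius * (ext / 2) * pi / 180,
                    outer_radius - inner_radius)
    if (border_band_width > max_band)
      stop("border_band_width exceeds the scar's angular/radial extent")
  }
  structure(spec, class = "phantom_spec")
}

scar_extent_deg <- function(spec) {
  ext <- (spec$scar_end_angle - spec$scar_start_angle) %% 360
  if (ext == 0 && spec$scar_end_angle != spec$scar_start_angle) ext <- 360
  ext
}

# Separable sinusoidal grating in coordinates rotated by `theta` degrees.
grating <- function(x, y, period, amplitude, theta = 0) {
  th <- theta * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  amplitude * sin(2 * pi * u / period) * sin(2 * pi * v / period)
}

#' Generate one synthetic cardiac phantom slice
#'
#' Rasterizes the annulus and scar sector of a [phantom_spec()] (a pixel
#' belongs to a region when its integer-coordinate center satisfies the
#' defining inequalities), fills each tissue with its grating plus mean
#' intensity, blends the two signals linearly across the border band, and adds
#' i.i.d. Gaussian noise everywhere.
#'
#' The returned ground truth splits the scar into `truth_core` (pure scar
#' texture) and `truth_border` (blended gray zone); their union is the scar
#' mask and they are disjoint.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `"phantom_slice"`: a list with `image` (numeric
#'   matrix), `annotation` (a [region_annotation()]), `truth_core`,
#'   `truth_border` (logical matrices) and `spec`.
#' @examples
#' sl <- generate_phantom(phantom_spec(seed = 7))
#' mean(sl$image[sl$annotation$scar]) > mean(sl$image[sl$annotation$myocardium &
#'   !sl$annotation$scar])
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  x <- col - spec$center[2]
  y <- spec$center[1] - row   # counterclockwise angles from the +x axis
  d <- sqrt(x^2 + y^2)
  theta <- (atan2(y, x) * 180 / pi) %% 360

  annulus <- d >= spec$inner_radius & d <= spec$outer_radius
  if (!any(annulus)) stop("degenerate geometry: empty annulus")

  ext <- scar_extent_deg(spec)
  if (ext > 0) {
    rel <- (theta - spec$scar_start_angle) %% 360
    in_sector <- rel <= ext
    scar <- annulus & in_sector
    if (!any(scar)) stop("degenerate geometry: scar sector contains no pixels")
    # arc-length distance (pixels) to the nearest angular scar edge
    edge_deg <- pmin(rel, ext - rel)
    arc <- d * edge_deg * pi / 180
    w <- if (spec$border_band_width > 0) pmin(arc / spec$border_band_width, 1) else
      (arc >= 0) * 1
    truth_core <- scar & (w >= 1)
    truth_border <- scar & !(w >= 1)
  } else {
    scar <- matrix(FALSE, n, n)
    truth_core <- scar
    truth_border <- scar
    w <- matrix(0, n, n)
  }

  healthy_sig <- spec$healthy_mean +
    grating(x, y, spec$texture_period_healthy, spec$texture_amplitude, 0)
  scar_sig <- spec$scar_mean +
    grating(x, y, spec$texture_period_scar, spec$texture_amplitude, 45)

  img <- matrix(0.05, n, n)          # dark background outside the annulus
  img[annulus] <- healthy_sig[annulus]
  if (any(scar)) img[scar] <- (w * scar_sig + (1 - w) * healthy_sig)[scar]

  set.seed(spec$seed)
  img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)

  structure(list(image = img,
                 annotation = region_annotation(annulus, scar, source = "mask_file"),
                 truth_core = truth_core,
                 truth_border = truth_border,
                 spec = spec),
            class = "phantom_slice")
}

#' Generate a synthetic two-group patient cohort
#'
#' Emulates the two patient groups of a case/control imaging study: `n_high`
#' patients drawn from `spec_high` and `n_low` from `spec_low` (typically
#' differing in scar extent and/or gray-zone band width), each contributing
#' `slices_per_patient` slices.  Per-slice seeds are derived deterministically
#' from the master seed, so the whole cohort is reproducible.
#'
#' @param n_high,n_low number of patients per group, `>= 1`.
#' @param spec_high,spec_low [phantom_spec()]s for the two groups (their `seed`
#'   field is overridden by the derived per-slice seed).
#' @param slices_per_patient slices per patient, `>= 1`.
#' @param seed master integer seed.
#' @return A list of patients; each patient is a list with `id`, `group`
#'   (`"high"` or `"low"`) and `slices` (a list of `phantom_slice`s).
#' @export
generate_cohort <- function(n_high, n_low, spec_high, spec_low,
                            slices_per_patient = 1L, seed = 1L) {
  if (n_high < 1 || n_low < 1) stop("each group needs at least one patient")
  if (slices_per_patient < 1) stop("slices_per_patient must be >= 1")
  groups <- c(rep("high", n_high), rep("low", n_low))
  patients <- vector("list", length(groups))
  for (p in seq_along(groups)) {
    base <- if (groups[p] == "high") spec_high else spec_low
    slices <- vector("list", slices_per_patient)
    for (s in seq_len(slices_per_patient)) {
      sp <- base
      sp$seed <- derive_seed(seed, p, s)
      slices[[s]] <- generate_phantom(sp)
    }
    patients[[p]] <- list(id = sprintf("%s_%02d", groups[p], p),
                          group = groups[p], slices = slices)
  }
  patients
}
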