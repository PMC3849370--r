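# Probability-interval ("LU") cardiac segments: a candidate segment is the
# set of myocardial pixels whose (sigmoid-extended) posterior lies in [L, U).
# Candidates are enumerated on a probability grid, each patient's relative
# segment size is accumulated over all slices, and the two patient groups are
# compared per candidate with a Mann-Whitney test.

#' Enumerate candidate (L, U) probability intervals
#'
#' All pairs with `L, U` on the grid `{0, step, 2 step, ..., 1}` and
#' `U - L >= min_width`.  With the defaults (step 0.025, minimum width 0.1)
#' there are 703 candidates.
#'
#' @param step grid increment; must divide 1 (within 1e-9).
#' @param min_width minimum interval width.
#' @return An object of class `"lu_grid"`: list with `step`, `min_width` and
#'   `candidates` (a data frame of `L`, `U`).
#' @export
lu_grid <- function(step = 0.025, min_width = 0.1) {
  if (step <= 0 || min_width < step || min_width > 1)
    stop("need 0 < step <= min_width <= 1")
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9) stop("step must divide 1")
  vals <- (0:n) * step
  idx <- which(outer(vals, vals, function(l, u) u - l >= min_width - 1e-12),
               arr.ind = TRUE)
  cand <- data.frame(L = vals[idx[, 1]], U = vals[idx[, 2]])
  cand <- cand[order(cand$L, cand$U), ]
  rownames(cand) <- NULL
  structure(list(step = step, min_width = min_width, candidates = cand),
            class = "lu_grid")
}

#' @export
print.lu_grid <- function(x, ...) {
  cat(sprintf("LU grid: step %.4g, min width %.4g, %d candidate segments\n",
              x$step, x$min_width, nrow(x$candidates)))
  invisible(x)
}

#' Sigmoid range extension of a probability map
#'
#' Probability maps rarely span the full 0-1 range; for comparability across
#' patients the map is passed through an order-preserving logistic rescale
#' `p' = plogis(g (p - c))` with center `c` at the midpoint of the observed
#' range and gain `g` chosen so the observed extremes map to 0.01 and 0.99.
#' A constant map is returned unchanged with a warning.
#'
#' @param map a [probability_map()].
#' @return The rescaled `"probability_map"`, defined values in `(0, 1)`.
#' @export
sigmoid_extend <- function(map) {
  v <- unclass(map)[!is.na(map)]
  if (length(v) < 2) stop("map needs at least 2 defined values")
  mn <- min(v)
  mx <- max(v)
  if (mx - mn < 1e-12) {
    warning("constant probability map; sigmoid extension skipped")
    return(map)
  }
  ctr <- (mn + mx) / 2
  gain <- stats::qlogis(0.99) / (mx - ctr)
  out <- unclass(map)
  out[!is.na(out)] <- stats::plogis(gain * (out[!is.na(out)] - ctr))
  attributes(out) <- attributes(map)
  out
}

# Half-open membership L <= p < U, with U = 1 inclusive so the top of the
# scale is covered; this makes a partition of [0, 1] out of adjacent segments.
in_segment <- function(p, l, u) {
  p >= l & (p < u | (u >= 1 & p <= 1))
}

#' Relative size of one cardiac segment for one patient
#'
#' Pixels with probability in `[L, U)` (`U = 1` inclusive) are accumulated
#' over all the patient's slices before dividing by the accumulated
#' myocardium size, so large and small slices are weighted by their pixel
#' counts.
#'
#' @param maps list of the patient's per-slice [probability_map()]s.
#' @param L,U interval bounds, `0 <= L < U <= 1`.
#' @return The relative size, a fraction in `[0, 1]`.
#' @export
segment_relative_size <- function(maps, L, U) {
  if (!is.null(dim(maps))) maps <- list(maps)
  num <- 0
  den <- 0
  for (m in maps) {
    p <- unclass(m)[!is.na(m)]
    num <- num + sum(in_segment(p, L, U))
    den <- den + length(p)
  }
  if (den == 0) stop("empty myocardium across all slices")
  num / den
}

#' Relative segment sizes for a whole cohort
#'
#' Computes every patient's relative size for every candidate segment of an
#' [lu_grid()] (via a per-patient histogram on the grid, equivalent to
#' [segment_relative_size()] per candidate).
#'
#' @param patient_maps named list: per patient, a list of that patient's
#'   per-slice [probability_map()]s.
#' @param groups character vector of group labels, one per patient.
#' @param grid an [lu_grid()].
#' @return A data frame with columns `patient`, `group`, `L`, `U`,
#'   `relative_size`, of class `"segment_size_table"`.
#' @export
segment_size_table <- function(patient_maps, groups, grid = lu_grid()) {
  stopifnot(length(patient_maps) == length(groups))
  if (is.null(names(patient_maps)))
    names(patient_maps) <- sprintf("patient_%02d", seq_along(patient_maps))
  n <- round(1 / grid$step)
  cand <- grid$candidates
  li <- as.integer(round(cand$L / grid$step)) + 1L
  ui <- as.integer(round(cand$U / grid$step)) + 1L
  rows <- lapply(seq_along(patient_maps), function(pi) {
    p <- unlist(lapply(patient_maps[[pi]], function(m) unclass(m)[!is.na(m)]))
    if (!length(p)) stop("patient ", names(patient_maps)[pi], " has no myocardium pixels")
    bin <- pmin(floor(p / grid$step), n - 1) + 1L   # p == 1 falls in the top bin
    cum <- c(0, cumsum(tabulate(bin, nbins = n)))
    sizes <- (cum[ui] - cum[li]) / length(p)
    data.frame(patient = names(patient_maps)[pi], group = groups[pi],
               L = cand$L, U = cand$U, relative_size = sizes)
  })
  structure(do.call(rbind, rows),
            class = c("segment_size_table", "data.frame"))
}

#' Mann-Whitney two-sample test
#'
#' The U statistic is the number of pairs `(a, b)` with `a > b` plus half the
#' tied pairs (equivalently computed from average ranks).  The two-sided
#' p-value is exact (from the null U distribution, identical to enumerating
#' all group-label assignments) when the smaller group has at most 8
#' observations and there are no ties, and otherwise uses the normal
#' approximation with the tie-corrected variance.  When every value is
#' identical across both groups, `p = 1`.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return A list with `statistic` (U for `group_a`) and `p_value`.
#' @export
mann_whitney <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1L)
    return(list(statistic = u, p_value = 1))
  if (!has_ties && min(n1, n2) <= 8) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 1 - stats::pwilcox(u - 1, n1, n2))
  } else {
    nn <- n1 + n2
    t_tab <- table(pooled)
    tie_term <- sum(t_tab^3 - t_tab) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u, p_value = min(p, 1))
}

#' Mann-Whitney significance map over the LU grid
#'
#' Per candidate segment, the two groups' relative sizes are compared with
#' [mann_whitney()]; the significance mask is `p < alpha` with no
#' multiple-testing correction by default (set `adjust = "BH"` for
#' Benjamini-Hochberg).
#'
#' @param table a [segment_size_table()] with exactly two groups, each with at
#'   least 2 patients.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame of class `"lu_test"` with columns `L`, `U`,
#'   `p_value`, `significant`.
#' @export
lu_significance_map <- function(table, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  grp <- unique(table$group)
  if (length(grp) != 2) stop("need exactly two groups")
  n_per <- table(unique(table[c("patient", "group")])$group)
  if (any(n_per < 2)) stop("each group needs at least 2 patients")
  key <- paste(table$L, table$U)
  segs <- !duplicated(key)
  out <- do.call(rbind, lapply(which(segs), function(i) {
    sel <- key == key[i]
    if (sum(sel) != sum(n_per))
      stop("missing relative sizes for some patients at segment (",
           table$L[i], ", ", table$U[i], ")")
    a <- table$relative_size[sel & table$group == grp[1]]
    b <- table$relative_size[sel & table$group == grp[2]]
    data.frame(L = table$L[i], U = table$U[i],
               p_value = mann_whitney(a, b)$p_value)
  }))
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("lu_test", "data.frame")
  out
}

#' Intensity-threshold baseline cardiac segments
#'
#' The baseline that skips probability mapping: with `m` the maximum
#' intensity over all scar pixels across the patient's slices, a pixel
#' belongs to the `(L, U)` segment iff it is myocardium and
#' `L*m <= I < U*m` (`U = 1` inclusive).
#'
#' @param images list of the patient's slice images.
#' @param annotations list of matching [region_annotation()]s.
#' @param L,U relative intensity bounds.
#' @return A list of logical masks, one per slice.
#' @export
intensity_baseline_segment <- function(images, annotations, L, U) {
  stopifnot(length(images) == length(annotations))
  scar_vals <- unlist(Map(function(im, an) im[an$scar], images, annotations))
  if (!length(scar_vals)) stop("no scar pixels in any slice")
  m <- max(scar_vals)
  Map(function(im, an) {
    an$myocardium & in_segment(im / m, L, U)
  }, images, annotations)
}

#' Plot an LU significance map
#'
#' Dot per candidate segment at coordinate `(L, U)`, filled where the group
#' difference is significant.
#'
#' @param x an `"lu_test"` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lu_test <- function(x, ...) {
  graphics::plot(x$L, x$U, pch = ifelse(x$significant, 19, 1),
                 col = ifelse(x$significant, "blue", "grey60"),
                 xlab = "L", ylab = "U", asp = 1, ...)
  graphics::legend("bottomright",
                   c(sprintf("p < %.3g", attr(x, "alpha")), "n.s."),
                   pch = c(19, 1), col = c("blue", "grey60"), bty = "n")
  invisible(x)
}
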