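# Internal helpers shared across modules.

# Shift a matrix by (di, dj); vacated cells get `fill`.
shift_matrix <- function(m, di, dj, fill = NA) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) + di
  src_c <- seq_len(nc) + dj
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Row-major offsets of an n x n window centered on a pixel: di varies slowest.
window_offsets <- function(n) {
  h <- (n - 1L) %/% 2L
  list(di = rep(-h:h, each = n), dj = rep(-h:h, times = n))
}

stopifnot_odd <- function(n, what = "window size") {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n %% 2 != 1)
    stop(what, " must be a positive odd integer, got ", n, call. = FALSE)
  as.integer(n)
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1, TRUE, FALSE)))
}

as_mask <- function(m) {
  storage.mode(m) <- "logical"
  m
}

# Derive a per-unit 31-bit seed from a master seed and structured indices.
derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) + 7919 * a + 104729 * b) %% 2147483647)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
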