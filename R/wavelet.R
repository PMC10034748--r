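# Orthonormal 3D Daubechies wavelet transform with periodic boundaries,
# implemented as explicit per-axis orthogonal matrices (grids here are small).
# Used as the sparsifying transform of the compressed-sensing baseline.

# Daubechies-4 (8-tap) synthesis lowpass filter
DB4_LO <- c(0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
            -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

# one-level periodic analysis matrix (n x n, orthonormal) for even n
dwt_step_matrix <- function(n, h = DB4_LO) {
  stopifnot(n %% 2 == 0, n >= 2)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # QMF highpass
  T <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    cols <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (j in seq_len(L)) {
      T[k, cols[j]] <- T[k, cols[j]] + h[j]
      T[n / 2 + k, cols[j]] <- T[n / 2 + k, cols[j]] + g[j]
    }
  }
  T
}

# apply matrix T to the first n entries of `arr` along `axis`
apply_axis <- function(arr, T, axis, n) {
  d <- dim(arr)
  idx <- lapply(d, seq_len); idx[[axis]] <- seq_len(n)
  sub <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(sub, perm)
  dm <- dim(m)
  dim(m) <- c(dm[1], prod(dm[2:3]))
  m <- T %*% m
  dim(m) <- dm
  sub <- aperm(m, order(perm))
  arr <- do.call(`[<-`, c(list(arr), idx, list(value = sub)))
  arr
}

max_wavelet_levels <- function(shape, filter_len = length(DB4_LO)) {
  lev <- 0
  n <- shape
  while (all(n %% 2 == 0) && all(n / 2 >= filter_len / 2) && lev < 8) {
    n <- n / 2; lev <- lev + 1
  }
  lev
}

#' Multi-level 3D orthonormal wavelet transform (periodic Daubechies-4)
#'
#' Separable periodic DWT; exactly orthonormal (`||Wx|| = ||x||`, `W^T W = I`).
#' Complex input is transformed channel-wise (real and imaginary parts).
#' `levels` is capped at what the grid size supports.
#'
#' @param x real or complex 3D array with even dimensions
#' @param levels decomposition levels
#' @return coefficient array of the same shape; attribute `levels`
#' @export
dwt3 <- function(x, levels = 3) {
  shape <- dim(x)
  levels <- min(levels, max_wavelet_levels(shape))
  if (levels < 1) stop("grid too small for a wavelet decomposition")
  n <- shape
  for (l in seq_len(levels)) {
    for (a in 1:3) x <- apply_axis(x, dwt_step_matrix(n[a]), a, n[a])
    n <- n %/% 2L
  }
  attr(x, "levels") <- levels
  x
}

#' @rdname dwt3
#' @param w coefficient array from [dwt3()]
#' @export
idwt3 <- function(w, levels = NULL) {
  shape <- dim(w)
  levels <- levels %||% attr(w, "levels") %||% 3
  ns <- lapply(seq_len(levels), function(l) shape %/% (2L^(l - 1L)))
  for (l in rev(seq_len(levels))) {
    n <- ns[[l]]
    for (a in 1:3) w <- apply_axis(w, t(dwt_step_matrix(n[a])), a, n[a])
  }
  attr(w, "levels") <- NULL
  w
}

#' Complex soft-thresholding (magnitude shrinkage)
#'
#' `x * max(1 - tau/|x|, 0)`: shrinks the magnitude by `tau`, preserving the
#' phase; real inputs reduce to ordinary soft-thresholding.
#'
#' @param x real or complex array
#' @param tau threshold (>= 0)
#' @return thresholded array
#' @export
soft_threshold <- function(x, tau) {
  m <- Mod(x)
  x * ifelse(m > tau, 1 - tau / pmax(m, .Machine$double.eps), 0)
}
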