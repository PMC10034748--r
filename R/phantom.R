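#' Create an image volume
#'
#' Light wrapper for a complex 3D array with voxel-size metadata. All
#' reconstruction routines accept plain complex arrays; the class only carries
#' metadata for I/O.
#'
#' @param data complex (or numeric) 3D array
#' @param voxel_size physical voxel size in mm (metadata only)
#' @return complex 3D array with class `image_volume`
#' @export
image_volume <- function(data, voxel_size = 1) {
  if (length(dim(data)) != 3) stop("image volume must be a 3D array")
  check_shape3(dim(data))
  if (!is.complex(data)) data <- data + 0i
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("image volume values must be finite")
  attr(data, "voxel_size") <- voxel_size
  class(data) <- c("image_volume", class(data))
  data
}

# centered voxel coordinate grids r = n - floor(N/2), one vector per axis
centered_coords <- function(shape) {
  lapply(1:3, function(a) seq_len(shape[a]) - 1 - floor(shape[a] / 2))
}

#' Add a hard ellipsoid to a magnitude volume
#'
#' Voxels with ((x-cx)/a)^2 + ((y-cy)/b)^2 + ((z-cz)/c)^2 <= 1 (centered voxel
#' coordinates) are incremented by `amplitude`. Axis aligned, exact indicator.
#'
#' @param mag real 3D array (modified copy returned)
#' @param center ellipsoid center in centered voxel coordinates
#' @param semi_axes per-axis semi-axes in voxels
#' @param amplitude added intensity
#' @return real 3D array
#' @export
add_ellipsoid <- function(mag, center, semi_axes, amplitude = 1) {
  shape <- dim(mag)
  cc <- centered_coords(shape)
  u <- outer(((cc[[1]] - center[1]) / semi_axes[1])^2,
             ((cc[[2]] - center[2]) / semi_axes[2])^2, "+")
  w <- ((cc[[3]] - center[3]) / semi_axes[3])^2
  inside <- outer(u, w, "+") <= 1
  mag + amplitude * inside
}

# rasterize a quadratic Bezier tube of given radius into a magnitude volume
add_tube <- function(mag, p0, p1, p2, radius, amplitude) {
  shape <- dim(mag)
  cc <- centered_coords(shape)
  t <- seq(0, 1, length.out = 4L * max(shape))
  pts <- outer((1 - t)^2, p0) + outer(2 * (1 - t) * t, p1) + outer(t^2, p2)
  hit <- array(FALSE, shape)
  r2 <- radius^2
  ir <- ceiling(radius)
  for (k in seq_along(t)) {
    p <- pts[k, ]
    ix <- which(abs(cc[[1]] - p[1]) <= ir)
    iy <- which(abs(cc[[2]] - p[2]) <= ir)
    iz <- which(abs(cc[[3]] - p[3]) <= ir)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (cc[[1]][ix] - p[1])^2
    dy2 <- (cc[[2]][iy] - p[2])^2
    dz2 <- (cc[[3]][iz] - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    hit[ix, iy, iz] <- hit[ix, iy, iz] | (d2 <= r2)
  }
  mag + amplitude * hit
}

# smooth low-frequency phase field over the volume
smooth_phase <- function(shape, n_modes = 3, max_cycles = 2, amp = pi / 2) {
  cc <- centered_coords(shape)
  phi <- array(0, shape)
  for (m in seq_len(n_modes)) {
    f <- stats::runif(3, -max_cycles, max_cycles)
    psi <- stats::runif(1, 0, 2 * pi)
    a <- stats::runif(1, 0, amp / n_modes)
    ph <- outer(outer(f[1] * cc[[1]] / shape[1], f[2] * cc[[2]] / shape[2], "+"),
                f[3] * cc[[3]] / shape[3], "+")
    phi <- phi + a * cos(2 * pi * ph + psi)
  }
  phi
}

#' Generate a synthetic vascular phantom
#'
#' Stand-in for contrast-enhanced pulmonary MRA anatomy: axis-aligned
#' ellipsoidal "organs" plus quadratic-Bezier tubular "vessels" of 1-3 voxel
#' radius, with a smooth complex phase. Magnitude is clipped to \[0, 1\].
#' Deterministic for a fixed seed.
#'
#' @param shape 3-vector of voxel counts (each >= 8)
#' @param n_ellipsoids number of random ellipsoids
#' @param n_tubes number of random tubes
#' @param seed RNG seed
#' @param voxel_size voxel size in mm (metadata)
#' @return complex `image_volume`
#' @export
make_phantom <- function(shape, n_ellipsoids = 3, n_tubes = 3, seed = 1,
                         voxel_size = 1) {
  shape <- check_shape3(shape)
  set.seed(seed)
  mag <- array(0, shape)
  half <- shape / 2
  for (e in seq_len(n_ellipsoids)) {
    center <- stats::runif(3, -0.35, 0.35) * shape
    axes <- stats::runif(3, 0.10, 0.28) * shape
    mag <- add_ellipsoid(mag, center, pmax(axes, 1.5),
                         amplitude = stats::runif(1, 0.3, 0.8))
  }
  for (tb in seq_len(n_tubes)) {
    p0 <- stats::runif(3, -0.45, 0.45) * shape
    p1 <- stats::runif(3, -0.45, 0.45) * shape
    p2 <- stats::runif(3, -0.45, 0.45) * shape
    mag <- add_tube(mag, p0, p1, p2, radius = stats::runif(1, 1, 3),
                    amplitude = stats::runif(1, 0.6, 1))
  }
  mag <- pmin(mag, 1)
  phi <- if (n_ellipsoids + n_tubes > 0) smooth_phase(shape) else array(0, shape)
  image_volume(mag * exp(1i * phi), voxel_size = voxel_size)
}

#' Simulate smooth coil sensitivity maps
#'
#' Gaussian sensitivity profiles centered on a ring of virtual coil elements
#' around the volume, each with a smooth complex phase ramp. With
#' `normalize = TRUE` the maps satisfy sum_c |S_c|^2 = 1 at every voxel.
#' `mode = "uniform"` returns all-ones maps (identity coil).
#'
#' @param shape 3-vector of voxel counts
#' @param n_channels number of receive channels (>= 1)
#' @param seed RNG seed
#' @param mode `"gaussian"` (default) or `"uniform"`
#' @param normalize root-sum-of-squares normalize per voxel
#' @return complex 4D array (Nx, Ny, Nz, n_channels) of class `coil_maps`
#' @export
make_coil_maps <- function(shape, n_channels, seed = 1,
                           mode = c("gaussian", "uniform"), normalize = TRUE) {
  shape <- check_shape3(shape)
  mode <- match.arg(mode)
  if (n_channels < 1) stop("n_channels must be >= 1")
  n_channels <- as.integer(n_channels)
  maps <- array(0i, c(shape, n_channels))
  if (mode == "uniform") {
    maps[] <- 1 + 0i
  } else {
    set.seed(seed)
    cc <- centered_coords(shape)
    for (c_i in seq_len(n_channels)) {
      # coil element on a ring/sphere just outside the volume
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      center <- u * 0.6 * shape
      sigma <- stats::runif(1, 0.5, 0.9) * mean(shape)
      a <- stats::runif(3, -0.5, 0.5) / shape   # gentle linear phase ramp
      g <- exp(-outer(outer((cc[[1]] - center[1])^2, (cc[[2]] - center[2])^2, "+"),
                      (cc[[3]] - center[3])^2, "+") / (2 * sigma^2))
      ramp <- outer(outer(a[1] * cc[[1]], a[2] * cc[[2]], "+"), a[3] * cc[[3]], "+")
      maps[, , , c_i] <- g * exp(2i * pi * ramp + 1i * stats::runif(1, 0, 2 * pi))
    }
    if (normalize) {
      sos <- sqrt(apply(Mod(maps)^2, 1:3, sum))
      for (c_i in seq_len(n_channels)) maps[, , , c_i] <- maps[, , , c_i] / sos
    }
  }
  class(maps) <- c("coil_maps", class(maps))
  maps
}
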