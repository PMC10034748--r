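# The multi-coil encoding operator E = scale * sqrt(dcf) . F_nu . S_c with its
# exact adjoint, spectral normalization by power iteration, and the gridded
# (adjoint) reconstruction.

#' Build a multi-coil encoding operator
#'
#' E maps an image volume to per-channel k-space samples:
#' `E_c x = scale * sqrt(dcf) * NUFFT(S_c * x)`. Density compensation enters
#' symmetrically (sqrt in the forward, sqrt in the adjoint), so the pair
#' (encode, encode_adjoint) is exactly adjoint and gradient steps on
#' `||Ex - y||^2` are dcf-preconditioned least squares.
#'
#' @param maps `coil_maps` 4D complex array (Nx, Ny, Nz, C)
#' @param traj `radial_traj`
#' @param dcf `radial_dcf` (defaults to [make_dcf()] of `traj`)
#' @param plan optional precomputed [make_nufft_plan()]
#' @param scale global scale factor (set by [normalize_operator()])
#' @param ... NUFFT options passed to [make_nufft_plan()]
#' @return object of class `encoding_op`
#' @export
encoding_op <- function(maps, traj, dcf = NULL, plan = NULL, scale = 1, ...) {
  shape <- dim(maps)[1:3]
  if (is.null(dcf)) dcf <- make_dcf(traj)
  if (is.null(plan)) plan <- make_nufft_plan(traj, shape, ...)
  stopifnot(length(dcf$weights) == plan$n_samples,
            nrow(traj$coords) == plan$n_samples)
  structure(list(maps = maps, traj = traj, dcf = dcf, plan = plan,
                 shape = shape, n_channels = dim(maps)[4],
                 scale = scale, sqrt_w = sqrt(dcf$weights),
                 normalized = FALSE),
            class = "encoding_op")
}

#' @export
print.encoding_op <- function(x, ...) {
  cat(sprintf("encoding operator: %s grid, %d channels, %d samples, scale %.4g%s\n",
              paste(x$shape, collapse = "x"), x$n_channels,
              x$plan$n_samples, x$scale,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Apply the encoding operator
#'
#' @param op an `encoding_op`
#' @param x complex 3D image array matching the operator grid
#' @return `kspace` in the operator (sqrt-dcf weighted, scaled) domain
#' @export
encode <- function(op, x) {
  stopifnot(inherits(op, "encoding_op"), all(dim(x)[1:3] == op$shape))
  s <- matrix(0i, op$n_channels, op$plan$n_samples)
  for (c_i in seq_len(op$n_channels))
    s[c_i, ] <- op$scale * op$sqrt_w *
      nufft_forward(op$maps[, , , c_i] * unclass(x), op$plan)
  kspace_data(s, weighted = TRUE)
}

#' Apply the adjoint encoding operator
#'
#' `E^H y = scale * sum_c conj(S_c) * NUFFT^H(sqrt(dcf) * y_c)`, the exact
#' conjugate transpose of [encode()].
#'
#' @param op an `encoding_op`
#' @param y `kspace` (or complex channel x sample matrix) in the operator domain
#' @return complex 3D image array
#' @export
encode_adjoint <- function(op, y) {
  s <- if (inherits(y, "kspace")) y$samples else y
  stopifnot(nrow(s) == op$n_channels, ncol(s) == op$plan$n_samples)
  x <- array(0i, op$shape)
  for (c_i in seq_len(op$n_channels))
    x <- x + Conj(op$maps[, , , c_i]) *
      nufft_adjoint(op$sqrt_w * s[c_i, ], op$plan)
  op$scale * x
}

#' Convert raw acquired k-space into the operator domain
#'
#' Applies the same sqrt(dcf) weighting and global scale that the operator
#' applies to images, so that the data-consistency fixed point is unchanged by
#' normalization. Idempotent via the `weighted` flag.
#'
#' @param op an `encoding_op`
#' @param y `kspace` with raw samples
#' @return `kspace` with `weighted = TRUE`
#' @export
prepare_kspace <- function(op, y) {
  stopifnot(inherits(y, "kspace"))
  if (y$weighted) return(y)
  kspace_data(sweep(y$samples, 2, op$scale * op$sqrt_w, "*"), weighted = TRUE)
}

# normal operator E^H E applied channel-by-channel (full dcf weighting)
ehe_apply <- function(op, x) {
  out <- array(0i, op$shape)
  for (c_i in seq_len(op$n_channels)) {
    s <- nufft_forward(op$maps[, , , c_i] * x, op$plan)
    out <- out + Conj(op$maps[, , , c_i]) *
      nufft_adjoint(op$dcf$weights * s, op$plan)
  }
  op$scale^2 * out
}

#' Largest eigenvalue of E^H E by power iteration
#'
#' @param op an `encoding_op`
#' @param n_iter maximum iterations (>= 1)
#' @param tol relative change convergence tolerance
#' @param seed seed for the random start vector
#' @return eigenvalue estimate; attributes `iterations` and `converged`.
#'   Warns (but returns the last estimate) on non-convergence.
#' @export
max_eig_power_iteration <- function(op, n_iter = 30, tol = 1e-5, seed = 0) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  v <- array(complex(real = stats::rnorm(prod(op$shape)),
                     imaginary = stats::rnorm(prod(op$shape))), op$shape)
  v <- v / cplx_norm(v)
  lam <- NA_real_; converged <- FALSE; it <- 0L
  for (it in seq_len(n_iter)) {
    w <- ehe_apply(op, v)
    # Rayleigh quotient: squares the convergence rate of the norm estimate
    lam_new <- real_dot(v, w)
    nw <- cplx_norm(w)
    if (nw == 0) { lam <- 0; converged <- TRUE; break }
    v <- w / nw
    if (!is.na(lam) && abs(lam_new - lam) < tol * lam_new) {
      lam <- lam_new; converged <- TRUE; break
    }
    lam <- lam_new
  }
  if (!converged && lam > 0)
    warning("power iteration did not converge within n_iter; returning last estimate")
  structure(lam, iterations = it, converged = converged)
}

#' Spectrally normalize the encoding operator
#'
#' Sets the global scale to 1/sqrt(lambda_max) so that ||E||_2 = 1. The same
#' scale must be applied to measured k-space ([prepare_kspace()] does this),
#' leaving the least-squares fixed point unchanged.
#'
#' @param op an `encoding_op`
#' @param n_iter,tol,seed power-iteration controls
#' @return normalized `encoding_op` (field `norm_lambda` records the estimate)
#' @export
normalize_operator <- function(op, n_iter = 30, tol = 1e-5, seed = 0) {
  lam <- as.numeric(max_eig_power_iteration(op, n_iter = n_iter, tol = tol, seed = seed))
  if (!is.finite(lam) || lam <= 0) stop("largest eigenvalue must be positive")
  op$scale <- op$scale / sqrt(lam)
  op$norm_lambda <- lam
  op$normalized <- TRUE
  op
}

#' Gridded (adjoint-NUFFT) reconstruction
#'
#' The density-compensated adjoint reconstruction `E^H y` of the (prepared)
#' acquired k-space: the canonical input to the unrolled model and the
#' baseline of the relative-difference metrics.
#'
#' @param op an `encoding_op`
#' @param y `kspace`, raw or prepared
#' @return complex 3D image array
#' @export
gridded_recon <- function(op, y) {
  encode_adjoint(op, prepare_kspace(op, y))
}
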