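# Forward simulation of multi-coil radial acquisitions and PCA coil
# compression.

#' Simulate a multi-coil non-Cartesian acquisition
#'
#' Per channel c, samples `NUFFT(S_c * x)` at the trajectory coordinates and
#' adds i.i.d. circular complex Gaussian noise of standard deviation
#' `noise_sigma` (total complex std; each real component has sd
#' `noise_sigma/sqrt(2)`). With `noise_sigma = 0` the output is deterministic
#' regardless of seed.
#'
#' @param x complex 3D image array (the ground-truth object)
#' @param maps `coil_maps` on the same grid
#' @param traj `radial_traj`
#' @param noise_sigma complex noise standard deviation (>= 0)
#' @param seed RNG seed for the noise
#' @param plan optional precomputed NUFFT plan for `traj` and the grid
#' @param ... NUFFT options
#' @return raw `kspace` (not dcf-weighted)
#' @export
simulate_acquisition <- function(x, maps, traj, noise_sigma = 0, seed = 1,
                                 plan = NULL, ...) {
  shape <- dim(x)
  if (!all(dim(maps)[1:3] == shape)) stop("coil maps do not match the image grid")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(plan)) plan <- make_nufft_plan(traj, shape, ...)
  n_ch <- dim(maps)[4]
  n <- plan$n_samples
  s <- matrix(0i, n_ch, n)
  for (c_i in seq_len(n_ch))
    s[c_i, ] <- nufft_forward(maps[, , , c_i] * unclass(x), plan)
  if (noise_sigma > 0) {
    set.seed(seed)
    s <- s + matrix(complex(real = stats::rnorm(n_ch * n, sd = noise_sigma / sqrt(2)),
                            imaginary = stats::rnorm(n_ch * n, sd = noise_sigma / sqrt(2))),
                    n_ch, n)
  }
  kspace_data(s, weighted = FALSE)
}

#' PCA coil compression
#'
#' Projects the channel dimension onto the top `n_out` principal components of
#' the sample-estimated channel covariance (via the SVD of the channel-by-
#' sample matrix). Total signal energy is non-increasing and is preserved when
#' `n_out` equals the channel count.
#'
#' @param y `kspace` with C channels
#' @param n_out number of virtual channels to keep (1 <= n_out <= C)
#' @return `kspace` with `n_out` channels; attribute `energy_kept` gives the
#'   retained energy fraction
#' @export
pca_coil_compress <- function(y, n_out) {
  stopifnot(inherits(y, "kspace"))
  if (n_out < 1) stop("n_out must be >= 1")
  if (n_out > y$n_channels) stop("n_out exceeds the channel count")
  sv <- svd(y$samples, nu = y$n_channels, nv = 0)
  comp <- Conj(t(sv$u[, seq_len(n_out), drop = FALSE])) %*% y$samples
  out <- kspace_data(comp, weighted = y$weighted)
  tot <- sum(Mod(y$samples)^2)
  attr(out, "energy_kept") <- if (tot > 0) sum(Mod(comp)^2) / tot else 1
  out
}
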