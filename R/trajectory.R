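# 3D radial ("kooshball") trajectories, analytic density compensation,
# and retrospective spoke subsampling.

bit_reverse <- function(i, n_bits) {
  out <- integer(length(i))
  for (b in seq_len(n_bits)) {
    out <- out * 2L + (i %% 2L)
    i <- i %/% 2L
  }
  out
}

#' Generate a center-out 3D radial trajectory
#'
#' Spoke directions follow a golden-means spherical spiral (approximately
#' uniform on the sphere); each spoke runs from k = 0 to |k| = grid_n/2 with
#' `n_readout` equally spaced samples. `ordering_mode = "bit_reversed"`
#' permutes the acquisition order by bit-reversal of the spoke index, a
#' stand-in for pseudorandom bit-reversed view ordering; `"sequential"` keeps
#' spiral order. Coordinates are in cycles/FOV, each component in
#' \[-grid_n/2, grid_n/2\].
#'
#' @param n_spokes number of radial spokes (>= 1)
#' @param n_readout samples per spoke (>= 2), k = 0 included
#' @param grid_n nominal reconstruction matrix size (k_max = grid_n/2)
#' @param ordering_mode `"bit_reversed"` (default) or `"sequential"`
#' @return object of class `radial_traj` with fields `coords` (n_samples x 3),
#'   `n_spokes`, `n_readout`, `grid_n`, `ordering` (spiral index of each
#'   acquired spoke), `spoke_of_sample`
#' @export
make_trajectory <- function(n_spokes, n_readout = NULL, grid_n = 32,
                            ordering_mode = c("bit_reversed", "sequential")) {
  ordering_mode <- match.arg(ordering_mode)
  if (n_spokes < 1) stop("n_spokes must be >= 1")
  if (is.null(n_readout)) n_readout <- grid_n
  if (n_readout < 2) stop("n_readout must be >= 2")
  n_spokes <- as.integer(n_spokes); n_readout <- as.integer(n_readout)

  j <- seq_len(n_spokes) - 1
  z <- 1 - 2 * (j + 0.5) / n_spokes
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * j / golden^2
  s <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(s * cos(phi), s * sin(phi), z)

  ordering <- if (ordering_mode == "bit_reversed" && n_spokes > 1) {
    n_bits <- ceiling(log2(n_spokes))
    rev_rank <- bit_reverse(0:(2L^n_bits - 1L), n_bits)
    (rev_rank[rev_rank < n_spokes] + 1L)[seq_len(n_spokes)]
  } else seq_len(n_spokes)
  # guard: bit-reversal of 0..2^b-1 is a permutation; filtering keeps < n_spokes
  ordering <- ordering[!is.na(ordering)]

  radii <- (seq_len(n_readout) - 1) / (n_readout - 1) * grid_n / 2
  dirs_acq <- dirs[ordering, , drop = FALSE]
  coords <- matrix(0, n_spokes * n_readout, 3)
  for (a in 1:3)
    coords[, a] <- as.vector(t(outer(dirs_acq[, a], radii)))

  structure(list(coords = coords, n_spokes = n_spokes, n_readout = n_readout,
                 grid_n = as.integer(grid_n), ordering = ordering,
                 ordering_mode = ordering_mode,
                 spoke_of_sample = rep(seq_len(n_spokes), each = n_readout)),
            class = "radial_traj")
}

#' @export
print.radial_traj <- function(x, ...) {
  cat(sprintf("3D radial trajectory: %d spokes x %d readout samples, grid %d, %s ordering\n",
              x$n_spokes, x$n_readout, x$grid_n, x$ordering_mode))
  invisible(x)
}

#' Analytic density compensation for 3D radial sampling
#'
#' Weights proportional to |k|^2 (exact analytic compensation for a 3D radial
#' geometry) with a positive floor at the k-space center equal to the weight
#' of the first nonzero readout sample. The global `scale` stays 1 until the
#' encoding operator is spectrally normalized.
#'
#' @param traj a `radial_traj`
#' @return list of class `radial_dcf` with `weights` (per sample, >= 0) and `scale`
#' @export
make_dcf <- function(traj) {
  stopifnot(inherits(traj, "radial_traj"))
  r <- sqrt(rowSums(traj$coords^2))
  r1 <- (traj$grid_n / 2) / (traj$n_readout - 1)   # first nonzero sample radius
  w <- pmax(r, r1)^2
  structure(list(weights = w, scale = 1, floor = r1^2), class = "radial_dcf")
}

#' Multi-coil k-space data container
#'
#' @param samples complex matrix, n_channels x n_samples
#' @param weighted logical; TRUE once the sqrt(dcf) * scale preconditioning of
#'   the encoding operator has been applied (operator-domain data)
#' @return object of class `kspace`
#' @export
kspace_data <- function(samples, weighted = FALSE) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.complex(samples)) samples <- samples + 0i
  structure(list(samples = samples, n_channels = nrow(samples),
                 n_samples = ncol(samples), weighted = weighted),
            class = "kspace")
}

#' Retrospectively subsample radial spokes
#'
#' Draws `n_keep` spokes uniformly at random without replacement, preserving
#' the original relative acquisition order, and recomputes the paired density
#' compensation for the subset. Emulates retrospective undersampling of a
#' densely acquired radial scan.
#'
#' @param y `kspace` data paired with `traj`, or NULL to subsample the
#'   trajectory alone
#' @param traj a `radial_traj`
#' @param n_keep number of spokes to keep (<= traj$n_spokes)
#' @param seed RNG seed
#' @return list with `kspace` (NULL if `y` was NULL), `traj`, `dcf`,
#'   `spoke_idx`, `sample_idx`
#' @export
subsample_spokes <- function(y, traj, n_keep, seed = 1) {
  stopifnot(inherits(traj, "radial_traj"))
  if (n_keep > traj$n_spokes) stop("n_keep exceeds the number of spokes")
  set.seed(seed)
  spoke_idx <- sort(sample.int(traj$n_spokes, n_keep))
  sample_idx <- as.vector(outer(seq_len(traj$n_readout),
                                (spoke_idx - 1L) * traj$n_readout, "+"))
  sub <- structure(list(coords = traj$coords[sample_idx, , drop = FALSE],
                        n_spokes = as.integer(n_keep),
                        n_readout = traj$n_readout, grid_n = traj$grid_n,
                        ordering = traj$ordering[spoke_idx],
                        ordering_mode = traj$ordering_mode,
                        spoke_of_sample = rep(seq_len(n_keep), each = traj$n_readout)),
                   class = "radial_traj")
  ysub <- NULL
  if (!is.null(y)) {
    stopifnot(inherits(y, "kspace"), y$n_samples == nrow(traj$coords))
    ysub <- kspace_data(y$samples[, sample_idx, drop = FALSE], weighted = y$weighted)
  }
  list(kspace = ysub, traj = sub, dcf = make_dcf(sub),
       spoke_idx = spoke_idx, sample_idx = sample_idx)
}
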