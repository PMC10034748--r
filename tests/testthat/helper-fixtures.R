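# Shared tiny fixtures, built in code. Everything is seeded and small enough
# to run in milliseconds; heavier end-to-end fixtures live in the tests that
# need them.

rel_err_t <- function(a, b) {
  d <- sqrt(sum(Mod(a - b)^2))
  n <- sqrt(sum(Mod(b)^2))
  if (n == 0) d else d / n
}

rand_cplx_vol <- function(shape, seed = 1) {
  set.seed(seed)
  n <- prod(shape)
  array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)), shape)
}

# small multi-coil radial problem on an 8^3 grid
tiny_problem <- function(n_channels = 2, n_spokes = 60, seed = 11,
                         shape = c(8, 8, 8), normalized = TRUE) {
  ph <- make_phantom(shape, n_ellipsoids = 2, n_tubes = 1, seed = seed)
  maps <- make_coil_maps(shape, n_channels, seed = seed + 1)
  traj <- make_trajectory(n_spokes, shape[1], shape[1])
  y <- simulate_acquisition(ph, maps, traj)
  op <- encoding_op(maps, traj)
  if (normalized)
    op <- suppressWarnings(normalize_operator(op, n_iter = 100, tol = 1e-9))
  list(phantom = ph, maps = maps, traj = traj, y = y, op = op, shape = shape)
}

# operator sampling every Cartesian grid frequency with unit dcf and a
# uniform single coil: E^H E is the identity up to NUFFT accuracy
cartesian_identity_op <- function(shape = c(8, 8, 8)) {
  ks <- expand.grid(kx = seq_len(shape[1]) - 1 - shape[1] / 2,
                    ky = seq_len(shape[2]) - 1 - shape[2] / 2,
                    kz = seq_len(shape[3]) - 1 - shape[3] / 2)
  coords <- as.matrix(ks)
  traj <- structure(list(coords = coords, n_spokes = nrow(coords),
                         n_readout = 1L, grid_n = shape[1],
                         ordering = seq_len(nrow(coords)),
                         ordering_mode = "sequential",
                         spoke_of_sample = seq_len(nrow(coords))),
                    class = "radial_traj")
  dcf <- structure(list(weights = rep(1, nrow(coords)), scale = 1, floor = 1),
                   class = "radial_dcf")
  maps <- make_coil_maps(shape, 1, mode = "uniform")
  encoding_op(maps, traj, dcf = dcf)
}
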