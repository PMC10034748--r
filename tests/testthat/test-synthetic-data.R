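# synthetic data generators: phantoms, coil maps, trajectories, density
# compensation, forward simulation, subsampling, coil compression

test_that("make_phantom: empty scene, ellipsoid voxel oracle, determinism", {
  z <- make_phantom(c(8, 8, 8), n_ellipsoids = 0, n_tubes = 0, seed = 1)
  expect_true(all(z == 0))

  # single centered ellipsoid vs brute-force voxel-wise indicator
  sh <- c(32, 32, 32)
  mag <- add_ellipsoid(array(0, sh), center = c(0, 0, 0),
                       semi_axes = c(8, 8, 8), amplitude = 1)
  cnt <- 0
  cc <- lapply(sh, function(n) seq_len(n) - 1 - n %/% 2)
  for (i in seq_len(32)) for (j in seq_len(32)) for (k in seq_len(32))
    if ((cc[[1]][i] / 8)^2 + (cc[[2]][j] / 8)^2 + (cc[[3]][k] / 8)^2 <= 1)
      cnt <- cnt + 1
  expect_identical(sum(mag == 1), as.integer(cnt))

  p1 <- make_phantom(c(16, 16, 16), seed = 42)
  p2 <- make_phantom(c(16, 16, 16), seed = 42)
  expect_identical(unclass(p1), unclass(p2))
  expect_true(max(Mod(p1)) <= 1 && min(Mod(p1)) >= 0)
  expect_true(any(Mod(p1) > 0))

  expect_error(make_phantom(c(4, 8, 8)), "shape")
})

test_that("make_coil_maps: uniform, SOS normalization, determinism", {
  u <- make_coil_maps(c(8, 8, 8), 1, mode = "uniform")
  expect_true(all(u == 1 + 0i))

  m <- make_coil_maps(c(12, 10, 8), 5, seed = 3, normalize = TRUE)
  sos <- apply(Mod(m)^2, 1:3, sum)
  expect_lt(max(abs(sos - 1)), 1e-6)

  m2 <- make_coil_maps(c(12, 10, 8), 5, seed = 3, normalize = TRUE)
  expect_identical(unclass(m), unclass(m2))

  expect_error(make_coil_maps(c(8, 8, 8), 0), "n_channels")
})

test_that("make_trajectory: spoke count, coordinate range, sphere uniformity", {
  # full acquisition size with a short readout (count is what matters)
  tr_big <- make_trajectory(94957, n_readout = 2, grid_n = 32)
  expect_identical(tr_big$n_spokes, 94957L)
  expect_true(all(sort(tr_big$ordering) == seq_len(94957)))  # permutation

  tr <- make_trajectory(500, 16, 16)
  expect_true(all(abs(tr$coords) <= 16 / 2 + 1e-12))
  # every spoke passes through k = 0
  k0 <- tr$coords[seq(1, nrow(tr$coords), by = tr$n_readout), ]
  expect_true(all(rowSums(abs(k0)) == 0))

  # Monte-Carlo uniformity bound: mean direction vector magnitude small
  tr4k <- make_trajectory(4096, 2, 32)
  tips <- tr4k$coords[seq(2, nrow(tr4k$coords), by = 2), ]
  dirs <- tips / sqrt(rowSums(tips^2))
  expect_lt(sqrt(sum(colMeans(dirs)^2)), 0.05)
})

test_that("make_dcf: non-negativity, |k|^2 law, center floor", {
  tr <- make_trajectory(40, 9, 16)        # radii 0, 1, 2, ..., 8
  d <- make_dcf(tr)
  expect_true(all(d$weights >= 0) && all(is.finite(d$weights)))
  r <- sqrt(rowSums(tr$coords^2))
  i_r <- which(abs(r - 8) < 1e-9)[1]
  i_r2 <- which(abs(r - 4) < 1e-9)[1]
  expect_lt(abs(d$weights[i_r] / d$weights[i_r2] - 4), 1e-9)
  i0 <- which(r == 0)
  expect_true(all(d$weights[i0] == d$floor) && d$floor > 0)
  expect_identical(d$scale, 1)
})

test_that("simulate_acquisition: zero input, impulse oracle, determinism", {
  sh <- c(8, 8, 8)
  maps <- make_coil_maps(sh, 1, mode = "uniform")
  tr <- make_trajectory(30, 8, 8)
  y0 <- simulate_acquisition(array(0i, sh), maps, tr)
  expect_true(all(y0$samples == 0))

  imp <- array(0i, sh); imp[5, 5, 5] <- 2  # centered origin voxel
  y <- simulate_acquisition(imp, maps, tr)
  oracle <- ndft_forward(imp, tr$coords)
  expect_lt(rel_err_t(y$samples[1, ], oracle), 1e-3)
  expect_lt(max(abs(Mod(y$samples) - 2 / sqrt(512))), 1e-3 * 2 / sqrt(512) + 1e-12)

  ph <- make_phantom(sh, 2, 1, seed = 2)
  ya <- simulate_acquisition(ph, maps, tr, noise_sigma = 0, seed = 1)
  yb <- simulate_acquisition(ph, maps, tr, noise_sigma = 0, seed = 999)
  expect_identical(ya$samples, yb$samples)

  expect_error(simulate_acquisition(ph, make_coil_maps(c(16, 16, 16), 1), tr),
               "grid")
})

test_that("simulate_acquisition is linear in the image", {
  sh <- c(8, 8, 8)
  maps <- make_coil_maps(sh, 2, seed = 5)
  tr <- make_trajectory(40, 8, 8)
  plan <- make_nufft_plan(tr, sh)
  x1 <- rand_cplx_vol(sh, 21); x2 <- rand_cplx_vol(sh, 22)
  a <- 1.3 - 0.4i; b <- -0.7 + 2i
  lhs <- simulate_acquisition(a * x1 + b * x2, maps, tr, plan = plan)$samples
  rhs <- a * simulate_acquisition(x1, maps, tr, plan = plan)$samples +
    b * simulate_acquisition(x2, maps, tr, plan = plan)$samples
  expect_lt(rel_err_t(lhs, rhs), 1e-6)
})

test_that("subsample_spokes: counts, identity subset, determinism, commutation", {
  tr <- make_trajectory(200, 8, 8)
  sh <- c(8, 8, 8)
  maps <- make_coil_maps(sh, 2, seed = 7)
  ph <- make_phantom(sh, 2, 1, seed = 8)
  y <- simulate_acquisition(ph, maps, tr)

  s <- subsample_spokes(y, tr, 50, seed = 4)
  expect_identical(s$traj$n_spokes, 50L)
  expect_identical(ncol(s$kspace$samples), 50L * tr$n_readout)
  expect_false(is.unsorted(s$spoke_idx))   # relative order preserved

  full <- subsample_spokes(y, tr, 200, seed = 4)
  expect_identical(full$kspace$samples, y$samples)

  s2 <- subsample_spokes(y, tr, 50, seed = 4)
  expect_identical(s$spoke_idx, s2$spoke_idx)

  expect_error(subsample_spokes(y, tr, 201), "exceeds")

  # subsample-then-simulate == simulate-then-subsample (noise 0), exactly
  y_sub_sim <- simulate_acquisition(ph, maps, s$traj)
  expect_equal(s$kspace$samples, y_sub_sim$samples, tolerance = 0)
})

test_that("pca_coil_compress: channel count, energy, rank-1 oracle", {
  sh <- c(8, 8, 8)
  maps <- make_coil_maps(sh, 6, seed = 9)
  tr <- make_trajectory(40, 8, 8)
  y <- simulate_acquisition(make_phantom(sh, 2, 1, seed = 10), maps, tr)

  y4 <- pca_coil_compress(y, 4)
  expect_identical(y4$n_channels, 4L)
  expect_lte(sum(Mod(y4$samples)^2), sum(Mod(y$samples)^2) * (1 + 1e-12))

  yfull <- pca_coil_compress(y, 6)
  expect_lt(abs(sum(Mod(yfull$samples)^2) / sum(Mod(y$samples)^2) - 1), 1e-6)

  # synthetic rank-1 data: every channel a scalar multiple of one signal
  set.seed(13)
  base <- complex(real = rnorm(300), imaginary = rnorm(300))
  wts <- complex(real = rnorm(5), imaginary = rnorm(5))
  r1 <- kspace_data(outer(wts, base))
  c1 <- pca_coil_compress(r1, 1)
  sv <- svd(r1$samples)$d
  expect_gt(attr(c1, "energy_kept"), 0.9999)
  expect_lt(abs(attr(c1, "energy_kept") - sv[1]^2 / sum(sv^2)), 1e-9)

  expect_error(pca_coil_compress(y, 0), "n_out")
  expect_error(pca_coil_compress(y, 7), "channel")
})
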