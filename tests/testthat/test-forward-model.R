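# encoding operator: NUFFT vs direct Fourier oracle, exact adjointness,
# spectral normalization, gridded reconstruction

test_that("nufft_forward matches the direct Fourier sum oracle", {
  sh <- c(8, 8, 8)
  x <- rand_cplx_vol(sh, 1)
  set.seed(2)
  coords <- matrix(runif(600, -4, 4), 200, 3)
  plan <- make_nufft_plan(coords, sh)

  expect_true(all(nufft_forward(array(0i, sh), plan) == 0))
  expect_lt(rel_err_t(nufft_forward(x, plan), ndft_forward(x, coords)), 1e-3)

  imp <- array(0i, sh); imp[5, 5, 5] <- 1
  s <- nufft_forward(imp, plan)
  expect_lt(max(abs(Mod(s) - 1 / sqrt(512))) / (1 / sqrt(512)), 1e-3)

  expect_error(make_nufft_plan(matrix(c(9, 0, 0), 1, 3), sh), "out of range")
})

test_that("nufft_adjoint is the exact adjoint and matches closed forms", {
  sh <- c(8, 10, 12)
  set.seed(3)
  coords <- cbind(runif(150, -4, 4), runif(150, -5, 5), runif(150, -6, 6))
  plan <- make_nufft_plan(coords, sh)
  x <- rand_cplx_vol(sh, 4)
  s <- complex(real = rnorm(150), imaginary = rnorm(150))

  expect_true(all(nufft_adjoint(rep(0i, 150), plan) == 0))
  lhs <- sum(Conj(nufft_forward(x, plan)) * s)
  rhs <- sum(Conj(x) * nufft_adjoint(s, plan))
  den <- sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(s)^2))
  expect_lt(abs(lhs - rhs) / den, 1e-6)

  # single k = 0 sample: exact closed form for the adjoint sum, NUFFT approx
  v <- 2 + 1i
  sh2 <- c(8, 8, 8)
  closed <- array(v / sqrt(512), sh2)
  expect_lt(rel_err_t(ndft_adjoint(v, matrix(0, 1, 3), sh2), closed), 1e-12)
  p0 <- make_nufft_plan(matrix(0, 1, 3), sh2)
  expect_lt(rel_err_t(nufft_adjoint(v, p0), closed), 1e-2)

  expect_error(nufft_adjoint(rep(0i, 10), plan), "sample count")
})

test_that("(encode, encode_adjoint) pass the adjoint test for varied setups", {
  for (cfgi in list(list(ch = 1, sp = 30, sh = c(8, 8, 8)),
                    list(ch = 3, sp = 50, sh = c(8, 10, 8)),
                    list(ch = 2, sp = 80, sh = c(12, 8, 10)))) {
    maps <- make_coil_maps(cfgi$sh, cfgi$ch, seed = cfgi$sp)
    tr <- make_trajectory(cfgi$sp, 8, 8)
    op <- encoding_op(maps, tr, scale = 1.7)
    x <- rand_cplx_vol(cfgi$sh, cfgi$sp + 1)
    set.seed(cfgi$sp + 2)
    yk <- kspace_data(matrix(complex(real = rnorm(cfgi$ch * op$plan$n_samples),
                                     imaginary = rnorm(cfgi$ch * op$plan$n_samples)),
                             cfgi$ch), weighted = TRUE)
    lhs <- sum(Conj(encode(op, x)$samples) * yk$samples)
    rhs <- sum(Conj(x) * encode_adjoint(op, yk))
    den <- sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(yk$samples)^2))
    expect_lt(abs(lhs - rhs) / den, 1e-6)
  }
})

test_that("encode reduces to nufft_forward for a trivial operator and matches
           the per-channel direct sum", {
  sh <- c(8, 8, 8)
  op1 <- cartesian_identity_op(sh)    # uniform coil, dcf = 1, scale 1
  x <- rand_cplx_vol(sh, 6)
  expect_identical(encode(op1, x)$samples[1, ], nufft_forward(x, op1$plan))

  # multi-coil brute force: per channel sqrt(dcf) * direct sum of S_c * x
  maps <- make_coil_maps(sh, 2, seed = 31)
  tr <- make_trajectory(40, 8, 8)
  op <- encoding_op(maps, tr)
  enc <- encode(op, x)$samples
  for (c_i in 1:2) {
    oracle <- op$sqrt_w * ndft_forward(maps[, , , c_i] * x, tr$coords)
    expect_lt(rel_err_t(enc[c_i, ], oracle), 1e-3)
  }
})

test_that("PSF of encode_adjoint . encode concentrates inside the phantom", {
  sh <- c(8, 8, 8)
  mag <- add_ellipsoid(array(0, sh), c(0, 0, 0), c(3, 3, 3), 1)
  ph <- mag + 0i
  maps <- make_coil_maps(sh, 2, seed = 41)
  tr <- make_trajectory(120, 8, 8)
  op <- encoding_op(maps, tr)
  out <- encode_adjoint(op, encode(op, ph))
  expect_true(mag[which.max(Mod(out))] > 0)
})

test_that("power iteration: identity case, dense eigensolver oracle", {
  op1 <- cartesian_identity_op(c(8, 8, 8))
  lam <- suppressWarnings(max_eig_power_iteration(op1, n_iter = 50, tol = 1e-8))
  expect_lt(abs(as.numeric(lam) - 1), 1e-3)

  # dense E^H E assembled column-by-column on a small problem
  sh <- c(8, 8, 8)
  maps <- make_coil_maps(sh, 2, seed = 51)
  tr <- make_trajectory(40, 8, 8)
  op <- encoding_op(maps, tr)
  n <- prod(sh)
  A <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    e <- array(0i, sh); e[j] <- 1
    A[, j] <- as.vector(bwlrecon:::ehe_apply(op, e))
  }
  lam_dense <- max(Re(eigen(A, only.values = TRUE)$values))
  lam_pi <- as.numeric(max_eig_power_iteration(op, n_iter = 300, tol = 1e-10))
  expect_lt(abs(lam_pi - lam_dense) / lam_dense, 1e-4)

  expect_warning(max_eig_power_iteration(op, n_iter = 2, tol = 1e-12),
                 "did not converge")
})

test_that("normalize_operator: unit spectral norm, idempotence, descent", {
  pb <- tiny_problem(n_channels = 2, n_spokes = 80, seed = 61, normalized = FALSE)
  op <- suppressWarnings(normalize_operator(pb$op, n_iter = 600, tol = 1e-12))
  lam <- as.numeric(suppressWarnings(
    max_eig_power_iteration(op, n_iter = 600, tol = 1e-12)))
  expect_lt(abs(lam - 1), 1e-3)

  op2 <- suppressWarnings(normalize_operator(op, n_iter = 600, tol = 1e-12))
  expect_lt(abs(op2$scale / op$scale - 1), 1e-3)

  # gradient step with unit step never increases the data fidelity
  y <- prepare_kspace(op, pb$y)
  fid <- function(x) sum(Mod(encode(op, x)$samples - y$samples)^2)
  for (s in 1:4) {
    x <- rand_cplx_vol(pb$shape, 70 + s)
    g <- encode_adjoint(op, kspace_data(encode(op, x)$samples - y$samples,
                                        weighted = TRUE))
    expect_lte(fid(x - g), fid(x) * (1 + 1e-9))
  }
})

test_that("gridded_recon: zero data, exact linearity, unitary Cartesian limit", {
  pb <- tiny_problem(n_channels = 2, n_spokes = 50, seed = 71)
  z <- gridded_recon(pb$op, kspace_data(matrix(0i, 2, pb$op$plan$n_samples)))
  expect_true(all(z == 0))

  a <- 2.5 - 1i
  g1 <- gridded_recon(pb$op, pb$y)
  ys <- kspace_data(a * pb$y$samples)
  expect_equal(gridded_recon(pb$op, ys), a * g1, tolerance = 1e-12)

  op1 <- cartesian_identity_op(c(8, 8, 8))
  x <- rand_cplx_vol(c(8, 8, 8), 72)
  y <- kspace_data(encode(op1, x)$samples, weighted = FALSE)
  expect_lt(rel_err_t(gridded_recon(op1, y), x), 1e-3)
})
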