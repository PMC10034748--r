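# unrolled model: channel conversion, regularizer properties, data
# consistency, reduction oracles, gradient fidelity

test_that("complex_to_channels: exact round trip and distance preservation", {
  x <- rand_cplx_vol(c(8, 9, 10), 1)
  ch <- complex_to_channels(x)
  expect_identical(channels_to_complex(ch), x)
  expect_identical(ch[, , , 1], Re(x))

  xr <- (array(rnorm(720), c(8, 9, 10)) + 0i)
  expect_true(all(complex_to_channels(xr)[, , , 2] == 0))

  y <- rand_cplx_vol(c(8, 9, 10), 2)
  d_ch <- sum((complex_to_channels(x) - complex_to_channels(y))^2)
  d_cx <- sum(Mod(x - y)^2)
  expect_lt(abs(d_ch - d_cx) / d_cx, 1e-12)
})

test_that("regularizer: identity at zero weights, bias-free zero map,
           receptive radius by perturbation", {
  cfg <- reg_config(channels = 3, n_res_blocks = 1, init_seed = 5)
  shape <- c(16, 16, 16)
  s1 <- plan_blocks(shape, 1, halo = 4)

  reg0 <- make_regularizer(cfg, init = "zero")
  x <- rand_cplx_vol(shape, 3)
  expect_equal(regularize(x, reg0, s1), x, tolerance = 0)

  reg <- make_regularizer(cfg, init = "kaiming")
  expect_identical(reg$receptive_radius, 4L)   # 4 conv layers
  expect_true(all(regularize(array(0i, shape), reg, s1) == 0))

  base <- regularize(x, reg, s1)
  xp <- x; xp[8, 8, 8] <- xp[8, 8, 8] + (1 + 1i)
  d <- Mod(regularize(xp, reg, s1) - base)
  idx <- which(d > 1e-12, arr.ind = TRUE)
  cheb <- apply(abs(sweep(idx, 2, c(8, 8, 8))), 1, max)
  expect_equal(max(cheb), 4)               # measured == analytic radius
})

test_that("dc_step: fixed point, joint-gradient oracle, fidelity descent", {
  pb <- tiny_problem(n_channels = 3, n_spokes = 70, seed = 81)
  op <- pb$op
  x <- rand_cplx_vol(pb$shape, 82)

  y_fix <- encode(op, x)               # exact Ex, already operator-domain
  expect_equal(dc_step(x, y_fix, op, t = 0.7), x, tolerance = 1e-12)

  y <- prepare_kspace(op, pb$y)
  # joint multi-channel gradient via the operator pair
  joint <- x - 0.9 * encode_adjoint(op, kspace_data(
    encode(op, x)$samples - y$samples, weighted = TRUE))
  expect_lt(rel_err_t(dc_step(x, y, op, t = 0.9), joint), 1e-6)

  fid <- function(v) sum(Mod(encode(op, v)$samples - y$samples)^2)
  for (s in 1:3) {
    xr <- rand_cplx_vol(pb$shape, 90 + s)
    expect_lt(fid(dc_step(xr, y, op, t = 1)), fid(xr))
  }

  expect_error(dc_step(rand_cplx_vol(c(8, 8, 10), 1), y, op, 1), "dim")
})

test_that("unrolled_reconstruct: N = 0 identity, zero-weight GD reduction,
           checkpointing equivalence", {
  pb <- tiny_problem(n_channels = 2, n_spokes = 60, seed = 91)
  op <- pb$op
  x0 <- gridded_recon(op, pb$y)

  m0 <- unrolled_model(0, pb$shape, cfg = reg_config(channels = 2,
                                                     n_res_blocks = 0))
  expect_identical(unrolled_reconstruct(x0, pb$y, op, m0), x0)

  # zero-weight regularizers: N unrolls == N plain gradient-descent steps
  cfg <- reg_config(channels = 3, n_res_blocks = 1, init_seed = 7)
  N <- 3
  mz <- unrolled_model(N, pb$shape, splits = 2, cfg = cfg)
  for (k in seq_len(N)) mz$regs[[k]] <- make_regularizer(cfg, init = "zero")
  mz$theta <- rep(bwlrecon:::softplus_inv(0.8), N)
  rec <- unrolled_reconstruct(x0, pb$y, op, mz)
  # bare gradient-descent oracle on 0.5||Ex - y||^2
  y <- prepare_kspace(op, pb$y)
  xg <- x0
  for (k in seq_len(N))
    xg <- xg - 0.8 * encode_adjoint(op, kspace_data(
      encode(op, xg)$samples - y$samples, weighted = TRUE))
  expect_lt(rel_err_t(rec, xg), 1e-6)

  mr <- unrolled_model(2, pb$shape, splits = 2,
                       cfg = reg_config(channels = 3, n_res_blocks = 1,
                                        init_seed = 9), reg_init = "kaiming")
  r1 <- unrolled_reconstruct(x0, pb$y, op, mr, checkpointed = TRUE)
  r2 <- unrolled_reconstruct(x0, pb$y, op, mr, checkpointed = FALSE)
  expect_lt(rel_err_t(r1, r2), 1e-6)
})

test_that("model gradients: checkpointed == end-to-end on a 16^3 2-coil
           1-unroll problem, and match finite differences", {
  shape <- c(16, 16, 16)
  ph <- make_phantom(shape, 2, 2, seed = 55)
  maps <- make_coil_maps(shape, 2, seed = 56)
  tr <- make_trajectory(150, 16, 16)
  y <- simulate_acquisition(ph, maps, tr)
  op <- suppressWarnings(normalize_operator(encoding_op(maps, tr),
                                            n_iter = 60, tol = 1e-8))
  cfg <- reg_config(channels = 4, n_res_blocks = 1, init_seed = 3)
  model <- unrolled_model(1, shape, splits = 2, cfg = cfg, reg_init = "kaiming")
  x0 <- gridded_recon(op, y)
  tgt <- unclass(ph)

  fb_c <- model_forward_backward(model, x0, y, op, tgt, checkpointed = TRUE)
  fb_n <- model_forward_backward(model, x0, y, op, tgt, checkpointed = FALSE)
  g_c <- bwlrecon:::grad_vec(model, fb_c)
  g_n <- bwlrecon:::grad_vec(model, fb_n)
  expect_lt(max(abs(g_c - g_n)) / max(abs(g_n)), 1e-6)
  expect_equal(fb_c$loss, fb_n$loss, tolerance = 1e-12)

  # finite-difference spot check (weights + step size)
  p <- bwlrecon:::model_params(model)
  lf <- function(v) mse_loss(unrolled_reconstruct(
    x0, y, op, bwlrecon:::model_set_params(model, v)), tgt)
  set.seed(6)
  for (i in c(sample(length(p) - 1, 3), length(p))) {
    eps <- 1e-5
    vp <- p; vp[i] <- vp[i] + eps
    vm <- p; vm[i] <- vm[i] - eps
    fd <- (lf(vp) - lf(vm)) / (2 * eps)
    expect_lt(abs(g_c[i] - fd) / max(abs(fd), 1e-8), 1e-3)
  }
})
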