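# block decomposition/recomposition, blockwise equivalence, checkpointed
# gradients, memory accounting

test_that("plan_blocks: printed counts, degenerate split, validation", {
  s <- plan_blocks(c(32, 32, 32), splits = c(2, 2, 2))
  expect_identical(s$n_blocks, 8L)
  expect_identical(s$n_internal_faces, 12L)

  s1 <- plan_blocks(c(16, 12, 8), splits = 1, halo = 3)
  expect_identical(s1$n_blocks, 1L)
  expect_identical(s1$n_internal_faces, 0L)
  expect_identical(s1$blocks[[1]]$ext, cbind(c(1L, 1L, 1L), c(16L, 12L, 8L)))

  expect_error(plan_blocks(c(8, 8, 8), splits = 9), "exceed")
  expect_error(plan_blocks(c(8, 8, 8), splits = 0), "splits")
  expect_error(plan_blocks(c(8, 8, 8), splits = 2, halo = -1), "halo")
})

test_that("plan_blocks tiles exactly with near-equal cores (randomized sweep)", {
  set.seed(5)
  for (rep in 1:12) {
    shape <- sample(8:23, 3, replace = TRUE)
    splits <- pmin(sample(1:4, 3, replace = TRUE), shape)
    s <- plan_blocks(shape, splits, halo = sample(0:3, 1))
    covered <- array(0L, shape)
    for (blk in s$blocks) {
      co <- blk$core
      covered[co[1, 1]:co[1, 2], co[2, 1]:co[2, 2], co[3, 1]:co[3, 2]] <-
        covered[co[1, 1]:co[1, 2], co[2, 1]:co[2, 2], co[3, 1]:co[3, 2]] + 1L
    }
    expect_true(all(covered == 1L))   # disjoint cores, full coverage
    for (a in 1:3) {
      sizes <- unique(vapply(s$blocks, function(b) b$core[a, 2] - b$core[a, 1] + 1L,
                             integer(1)))
      expect_lte(diff(range(sizes)), 1L)
    }
  }
})

test_that("extract_patches / recompose: partition, corner zero-padding oracle,
           round trip", {
  x <- rand_cplx_vol(c(16, 16, 16), 8)
  s0 <- plan_blocks(c(16, 16, 16), 2, halo = 0)
  ps <- extract_patches(x, s0)
  expect_identical(dim(ps[[1]]), c(8L, 8L, 8L))
  expect_identical(recompose(ps, s0), x)   # bitwise partition round trip

  # corner block with halo 2: 12^3 patch, exterior faces zero-filled
  s2 <- plan_blocks(c(16, 16, 16), 2, halo = 2)
  p1 <- extract_patches(x, s2)[[1]]
  expect_identical(dim(p1), c(12L, 12L, 12L))
  # brute-force index map oracle
  oracle <- array(0i, c(12, 12, 12))
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    src <- c(i, j, k) - 2            # patch voxel -> volume voxel
    if (all(src >= 1) && all(src <= 16)) oracle[i, j, k] <- x[src[1], src[2], src[3]]
  }
  expect_identical(p1, oracle)

  expect_true(all(extract_patches(array(0i, c(16, 16, 16)), s2)[[5]] == 0))

  # round-trip identity for random (shape, splits, halo)
  set.seed(9)
  for (rep in 1:10) {
    shape <- sample(8:20, 3, replace = TRUE)
    s <- plan_blocks(shape, pmin(sample(1:3, 3, TRUE), shape), halo = sample(0:4, 1))
    xr <- rand_cplx_vol(shape, 100 + rep)
    expect_identical(recompose(extract_patches(xr, s), s), xr)
  }

  expect_error(extract_patches(x, plan_blocks(c(8, 8, 8), 2)), "shape")
  expect_error(recompose(ps[1:3], s0), "patch count")
})

test_that("recompose discards halo bleed-through (block-index label map)", {
  s <- plan_blocks(c(10, 9, 8), c(2, 3, 2), halo = 2)
  patches <- lapply(seq_len(s$n_blocks), function(b)
    array(b + 0i, s$blocks[[b]]$patch_shape))
  lab <- recompose(patches, s)
  oracle <- array(0i, c(10, 9, 8))
  for (b in seq_len(s$n_blocks)) {
    co <- s$blocks[[b]]$core
    oracle[co[1, 1]:co[1, 2], co[2, 1]:co[2, 2], co[3, 1]:co[3, 2]] <- b
  }
  expect_identical(lab, oracle)
})

test_that("blockwise_apply: identity, single-conv full-volume oracle, halo-0
           negative control", {
  x <- rand_cplx_vol(c(16, 16, 16), 10)
  s <- plan_blocks(c(16, 16, 16), 2, halo = 1)
  out <- blockwise_apply(x, function(p) p, s)
  expect_identical(as.vector(out), as.vector(x))

  # single zero-padded 3x3x3 convolution applied to Re/Im channels
  set.seed(11)
  w <- array(rnorm(27 * 2 * 2), c(3, 3, 3, 2, 2))
  conv_op <- list(forward = function(p) {
    channels_to_complex(bwlrecon:::conv3d_forward(complex_to_channels(p), w))
  }, receptive_radius = 1)
  full <- conv_op$forward(x)
  bw <- blockwise_apply(x, conv_op, s)
  expect_lt(rel_err_t(bw, full), 1e-6)

  # halo 0: mismatch strictly confined to within 1 voxel of internal faces
  s0 <- plan_blocks(c(16, 16, 16), 2, halo = 0)
  bw0 <- blockwise_apply(x, conv_op, s0, override_halo_check = TRUE)
  diffmask <- Mod(bw0 - full) > 1e-12
  near_face <- array(FALSE, c(16, 16, 16))
  near_face[8:9, , ] <- TRUE; near_face[, 8:9, ] <- TRUE; near_face[, , 8:9] <- TRUE
  expect_true(all(!diffmask | near_face))
  expect_true(any(diffmask))   # negative control actually bites

  expect_error(blockwise_apply(x, conv_op, s0), "receptive radius")
})

test_that("equivalence theorem: conv/Leaky-ReLU nets, halo >= radius, 20+ configs", {
  set.seed(12)
  for (rep in 1:20) {
    shape <- sample(c(8, 9, 10, 12, 14), 3, replace = TRUE)
    splits <- pmin(sample(1:3, 3, TRUE), 2)
    cfg <- reg_config(channels = sample(2:4, 1),
                      n_res_blocks = sample(0:1, 1),
                      init_seed = 1000 + rep)
    reg <- make_regularizer(cfg, init = "kaiming")
    s <- plan_blocks(shape, splits, halo = reg$receptive_radius)
    x <- rand_cplx_vol(shape, 2000 + rep)
    full <- regularize(x, reg, plan_blocks(shape, 1, halo = reg$receptive_radius))
    bw <- regularize(x, reg, s)
    expect_lt(rel_err_t(bw, full), 1e-5)
  }
})

test_that("checkpointed and cached blockwise gradients agree (2-layer net)", {
  cfg <- reg_config(channels = 3, n_res_blocks = 0, init_seed = 77) # 2 convs
  reg <- make_regularizer(cfg, init = "kaiming")
  shape <- c(12, 12, 12)
  s <- plan_blocks(shape, 2, halo = reg$receptive_radius)
  x <- rand_cplx_vol(shape, 30)
  g <- rand_cplx_vol(shape, 31)
  z <- regularize(x, reg, s, checkpointed = FALSE)
  b_cached <- regularize_backward(x, reg, s, g, caches = attr(z, "cache"))
  b_ckpt <- regularize_backward(x, reg, s, g)
  expect_lt(rel_err_t(b_ckpt$gx, b_cached$gx), 1e-6)
  gv1 <- bwlrecon:::weights_to_vec(b_ckpt$gw)
  gv2 <- bwlrecon:::weights_to_vec(b_cached$gw)
  expect_lt(max(abs(gv1 - gv2)) / max(abs(gv2)), 1e-6)
})

test_that("peak working set is one extended patch plus two volumes", {
  x <- rand_cplx_vol(c(16, 16, 16), 40)
  s <- plan_blocks(c(16, 16, 16), 2, halo = 2)
  f <- list(forward = function(p) p, receptive_radius = 0,
            activations_per_voxel = 5)
  out <- blockwise_apply(x, f, s)
  mem <- attr(out, "memory")
  V <- 16^3
  expect_identical(mem$volume_elements, V)
  expect_identical(mem$max_patch_elements, 5 * 12^3)  # core 8 + halo 2 per side
  expect_lte(mem$peak_live_elements, 2 * V + 5 * 12^3)
})

test_that("memory_footprint reproduces the analytic scaling formulas", {
  s <- plan_blocks(c(300, 300, 300), 2, halo = 0)
  V <- 300^3
  m5 <- memory_footprint(c(300, 300, 300), s, n_unrolls = 5)
  expect_identical(m5$forward_volume_elements, 6 * V)
  expect_identical(m5$reduction_factor, 8)

  m0 <- memory_footprint(c(300, 300, 300), s, n_unrolls = 0)
  expect_identical(m0$forward_volume_elements, V)

  sh <- plan_blocks(c(32, 32, 32), 2, halo = 3)
  mh <- memory_footprint(c(32, 32, 32), sh, n_unrolls = 2,
                         activations_per_voxel = 7)
  expect_identical(mh$backward_total_elements,
                   3 * 32^3 + sum(7 * vapply(sh$blocks, function(b)
                     prod(as.numeric(b$patch_shape)), numeric(1))))
})
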