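# Seeded desk-scale replicas of the experimental designs: the unroll-count
# study, the spokes sweep with a single model, and the method comparison.
# All stages are deterministic functions of the spec seed.

#' Desk-scale experiment specification
#'
#' Defaults are sized so the full suite runs on one CPU in minutes: 32^3
#' volumes, 4 coils, a 3000-spoke dense reference acquisition (about the 3D
#' radial Nyquist count at this matrix size), 300-spoke undersampled inputs
#' (10x undersampling, mirroring the 5k-of-95k regime), 200 training
#' iterations, and a thin (6-channel, 1-res-block) regularizer. Every field
#' scales up to the full-size configuration (300-450 grids, 20 coils,
#' 32-channel regularizer, 5 unrolls, 4000 iterations).
#'
#' @param shape volume shape
#' @param n_coils receive channels
#' @param n_dense_spokes spokes in the dense reference acquisition
#' @param n_readout readout samples per spoke
#' @param spokes_per_example spokes per undersampled training/test example
#' @param n_train_phantoms,n_test_phantoms synthetic cohort sizes
#' @param unrolls unroll counts for the unroll study (0 = network-only arm)
#' @param budgets spoke budgets for the sweep (model trained at the smallest)
#' @param train_iterations,learning_rate training budget
#' @param channels,n_res_blocks,splits regularizer size and block splits
#' @param noise_sigma complex noise std of the simulated acquisition
#' @param proxy supervision/reference mode: `"phantom"` (clean object) or
#'   `"cgsense"` (30-iteration CG-SENSE of the dense data)
#' @param cg_iters CG iterations of the proxy reconstruction
#' @param power_iter power-iteration count for per-subset normalization
#'   (reduced from 30 for desk-scale runtime; the residual scale error is a
#'   fraction of a percent and shared by all arms)
#' @param seed master seed
#' @param out_dir optional directory for CSV/JSON artifacts
#' @return list of class `experiment_spec`
#' @export
experiment_spec <- function(shape = c(32, 32, 32), n_coils = 4,
                            n_dense_spokes = 3000, n_readout = NULL,
                            spokes_per_example = 300,
                            n_train_phantoms = 2, n_test_phantoms = 5,
                            unrolls = c(0, 1, 3, 5),
                            budgets = c(300, 450, 600, 900),
                            train_iterations = 200, learning_rate = 1e-3,
                            channels = 6, n_res_blocks = 1, splits = 1,
                            noise_sigma = 0,
                            proxy = c("phantom", "cgsense"), cg_iters = 30,
                            power_iter = 8, seed = 1, out_dir = NULL) {
  structure(list(shape = check_shape3(shape), n_coils = n_coils,
                 n_dense_spokes = n_dense_spokes,
                 n_readout = n_readout %||% shape[1],
                 spokes_per_example = spokes_per_example,
                 n_train_phantoms = n_train_phantoms,
                 n_test_phantoms = n_test_phantoms,
                 unrolls = unrolls, budgets = budgets,
                 train_iterations = train_iterations,
                 learning_rate = learning_rate,
                 channels = channels, n_res_blocks = n_res_blocks,
                 splits = splits, noise_sigma = noise_sigma,
                 proxy = match.arg(proxy), cg_iters = cg_iters,
                 power_iter = power_iter, seed = seed, out_dir = out_dir),
            class = "experiment_spec")
}

#' Generate the full synthetic experiment world from a spec
#'
#' Phantoms, coil maps, the dense trajectory and its NUFFT plan, dense
#' k-space per phantom, and the proxy reference volumes. Deterministic in
#' `spec$seed`.
#'
#' @param spec an [experiment_spec()]
#' @return list with `train` / `test` example lists (fields `phantom`,
#'   `kspace`, `reference`, plus shared `traj`, `maps`, `plan`)
#' @export
make_experiment_data <- function(spec) {
  seeds <- derive_seeds(spec$seed, 3 + spec$n_train_phantoms + spec$n_test_phantoms)
  maps <- make_coil_maps(spec$shape, spec$n_coils, seed = seeds[1])
  traj <- make_trajectory(spec$n_dense_spokes, spec$n_readout, spec$shape[1])
  plan <- make_nufft_plan(traj, spec$shape)
  build <- function(sd, idx) {
    ph <- make_phantom(spec$shape, n_ellipsoids = 3, n_tubes = 3, seed = sd)
    ks <- simulate_acquisition(ph, maps, traj, noise_sigma = spec$noise_sigma,
                               seed = sd + 1L, plan = plan)
    ref <- if (spec$proxy == "phantom") unclass(ph) else {
      op <- suppressWarnings(normalize_operator(
        encoding_op(maps, traj, plan = plan), n_iter = spec$power_iter))
      cg_sense(ks, op, n_iters = spec$cg_iters)
    }
    list(phantom = ph, kspace = ks, reference = ref, traj = traj,
         maps = maps, plan = plan, target = ref)
  }
  train_ex <- lapply(seq_len(spec$n_train_phantoms),
                     function(i) build(seeds[3 + i], i))
  test_ex <- lapply(seq_len(spec$n_test_phantoms),
                    function(i) build(seeds[3 + spec$n_train_phantoms + i], i))
  list(train = train_ex, test = test_ex, traj = traj, maps = maps,
       plan = plan, seeds = seeds)
}

# build the undersampled test problem for test case i (shared across arms)
test_problem <- function(data, spec, i, n_spokes = NULL) {
  seeds <- derive_seeds(spec$seed + 7777L, length(data$test) * length(spec$budgets) + 64L)
  ex <- data$test[[i]]
  tex <- make_training_example(
    ex$kspace, ex$traj,
    list(maps = ex$maps, plan = ex$plan, target = ex$reference,
         power_iter = spec$power_iter),
    n_spokes = n_spokes %||% spec$spokes_per_example, seed = seeds[i])
  tex
}

train_arm_model <- function(spec, data, n_unrolls) {
  cfg <- reg_config(channels = spec$channels, n_res_blocks = spec$n_res_blocks,
                    init_seed = spec$seed)
  model <- if (n_unrolls == 0)
    unrolled_model(1, spec$shape, splits = spec$splits, cfg = cfg,
                   dc_enabled = FALSE)
  else
    unrolled_model(n_unrolls, spec$shape, splits = spec$splits, cfg = cfg)
  tcfg <- train_config(learning_rate = spec$learning_rate,
                       n_iterations = spec$train_iterations,
                       spokes_per_example = spec$spokes_per_example,
                       seed = spec$seed + 101L,
                       power_iter = spec$power_iter)
  train(model, data$train, tcfg)
}

write_artifacts <- function(spec, name, table, summary = NULL) {
  if (is.null(spec$out_dir)) return(invisible(NULL))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, file.path(spec$out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
  if (!is.null(summary))
    jsonlite::write_json(summary, file.path(spec$out_dir, paste0(name, ".json")),
                         digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' Unroll-count study
#'
#' Trains one model per unroll setting (0 = network-only regularizer with no
#' data consistency) with identical seeds and budgets, evaluates all arms on
#' the same undersampled test subsets, and reports PSNR/SSIM relative
#' differences plus the paired t-test between the largest and smallest arms.
#'
#' @param spec an [experiment_spec()]
#' @param data optional pre-built [make_experiment_data()] world
#' @param verbose print progress
#' @return list of class `unroll_study`: `table` (per case x arm),
#'   `summary` (per arm means), `t_test_psnr`, `t_test_ssim`, `fits`
#' @export
run_unroll_study <- function(spec, data = NULL, verbose = FALSE) {
  stopifnot(length(spec$unrolls) >= 2)
  if (is.null(data)) data <- make_experiment_data(spec)
  n_test <- length(data$test)
  problems <- lapply(seq_len(n_test), function(i) test_problem(data, spec, i))
  rows <- list(); fits <- list()
  for (u in spec$unrolls) {
    if (verbose) message("training arm: ", u, " unrolls")
    fit <- train_arm_model(spec, data, u)
    fits[[as.character(u)]] <- fit
    for (i in seq_len(n_test)) {
      pr <- problems[[i]]
      recon <- unrolled_reconstruct(pr$input, pr$kspace, pr$op, fit$model)
      m <- relative_difference(recon, pr$input, data$test[[i]]$reference)
      rows[[length(rows) + 1L]] <-
        data.frame(unrolls = u, case = i, psnr = m$psnr, ssim = m$ssim,
                   psnr_gridded = m$psnr_gridded, ssim_gridded = m$ssim_gridded,
                   psnr_rel = m$psnr_rel, ssim_rel = m$ssim_rel)
    }
  }
  table <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(psnr_rel, ssim_rel) ~ unrolls, table, mean)
  hi <- table[table$unrolls == max(spec$unrolls), ]
  lo <- table[table$unrolls == min(spec$unrolls), ]
  tt_p <- paired_t_test(hi$psnr_rel, lo$psnr_rel)
  tt_s <- paired_t_test(hi$ssim_rel, lo$ssim_rel)
  out <- structure(list(table = table, summary = summary,
                        t_test_psnr = tt_p, t_test_ssim = tt_s, fits = fits),
                   class = "unroll_study")
  write_artifacts(spec, "unroll_study", table,
                  list(summary = summary, t_test_psnr = tt_p, t_test_ssim = tt_s))
  out
}

#' Spoke-budget sweep with a single trained model
#'
#' Applies one model (trained at the smallest budget, never retrained) across
#' all spoke budgets and reports absolute and relative PSNR/SSIM per budget.
#'
#' @param spec an [experiment_spec()]
#' @param fit optional `train_fit` (trained at `min(spec$budgets)`)
#' @param data optional pre-built world
#' @param n_unrolls unrolls of the model trained when `fit` is NULL
#' @return list: `table`, `fit`
#' @export
run_spokes_sweep <- function(spec, fit = NULL, data = NULL, n_unrolls = 5) {
  if (is.null(data)) data <- make_experiment_data(spec)
  if (is.null(fit)) {
    spec_train <- spec
    spec_train$spokes_per_example <- min(spec$budgets)
    fit <- train_arm_model(spec_train, data, n_unrolls)
  }
  rows <- list()
  for (b in spec$budgets) {
    for (i in seq_along(data$test)) {
      pr <- test_problem(data, spec, i, n_spokes = b)
      recon <- unrolled_reconstruct(pr$input, pr$kspace, pr$op, fit$model)
      m <- relative_difference(recon, pr$input, data$test[[i]]$reference)
      rows[[length(rows) + 1L]] <-
        data.frame(n_spokes = b, case = i, psnr = m$psnr, ssim = m$ssim,
                   psnr_gridded = m$psnr_gridded, ssim_gridded = m$ssim_gridded,
                   psnr_rel = m$psnr_rel, ssim_rel = m$ssim_rel)
    }
  }
  table <- do.call(rbind, rows)
  write_artifacts(spec, "spokes_sweep", table)
  list(table = table, fit = fit)
}

#' Method comparison: gridded vs L1-wavelet CS vs MBDL
#'
#' Evaluates all methods on identical undersampled subsets against the proxy
#' reference, with paired t-tests on the relative differences and
#' informational wall times.
#'
#' @param spec an [experiment_spec()]
#' @param fit optional trained `train_fit` for the MBDL arm
#' @param data optional pre-built world
#' @param cs a [cs_config()] for the CS arm
#' @return list: `table`, `t_tests`, `wall_times` (seconds per method)
#' @export
run_method_comparison <- function(spec, fit = NULL, data = NULL,
                                  cs = cs_config()) {
  if (is.null(data)) data <- make_experiment_data(spec)
  if (is.null(fit)) fit <- train_arm_model(spec, data, 5)
  rows <- list(); wall <- c(gridded = 0, l1_wavelet = 0, mbdl = 0)
  for (i in seq_along(data$test)) {
    pr <- test_problem(data, spec, i)
    ref <- data$test[[i]]$reference
    t0 <- Sys.time()
    m_g <- relative_difference(pr$input, pr$input, ref)
    wall["gridded"] <- wall["gridded"] + as.numeric(Sys.time() - t0, units = "secs")
    t0 <- Sys.time()
    cs_rec <- l1_wavelet_cs(pr$kspace, pr$op, cs)
    wall["l1_wavelet"] <- wall["l1_wavelet"] + as.numeric(Sys.time() - t0, units = "secs")
    m_c <- relative_difference(cs_rec, pr$input, ref)
    t0 <- Sys.time()
    dl_rec <- unrolled_reconstruct(pr$input, pr$kspace, pr$op, fit$model)
    wall["mbdl"] <- wall["mbdl"] + as.numeric(Sys.time() - t0, units = "secs")
    m_d <- relative_difference(dl_rec, pr$input, ref)
    for (meth in list(list("gridded", m_g), list("l1_wavelet", m_c),
                      list("mbdl", m_d)))
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth[[1]], case = i,
                   psnr = meth[[2]]$psnr, ssim = meth[[2]]$ssim,
                   psnr_rel = meth[[2]]$psnr_rel, ssim_rel = meth[[2]]$ssim_rel)
  }
  table <- do.call(rbind, rows)
  pick <- function(m, col) table[table$method == m, col]
  t_tests <- list(
    mbdl_vs_cs_psnr = paired_t_test(pick("mbdl", "psnr_rel"), pick("l1_wavelet", "psnr_rel")),
    mbdl_vs_cs_ssim = paired_t_test(pick("mbdl", "ssim_rel"), pick("l1_wavelet", "ssim_rel")))
  write_artifacts(spec, "method_comparison", table, list(t_tests = t_tests,
                                                         wall_times = as.list(wall)))
  list(table = table, t_tests = t_tests, wall_times = wall)
}
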