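# Supervised end-to-end training with per-iteration retrospective spoke
# subsampling, MSE loss and Adam.

#' Training configuration
#'
#' @param learning_rate Adam learning rate
#' @param n_iterations number of training iterations
#' @param optimizer only `"adam"` (moments 0.9/0.999, eps 1e-8, no schedule)
#' @param spokes_per_example spokes drawn per training example
#' @param seed master seed for the subsampling stream
#' @param checkpointed block-wise + channel-wise checkpointing flag
#' @param power_iter,power_tol power-iteration controls for per-subset
#'   operator normalization
#' @return list of class `train_config`
#' @export
train_config <- function(learning_rate = 1e-3, n_iterations = 4000,
                         optimizer = "adam", spokes_per_example = 5000,
                         seed = 1, checkpointed = TRUE,
                         power_iter = 30, power_tol = 1e-5) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(n_iterations >= 1, spokes_per_example >= 1, learning_rate >= 0)
  structure(list(learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations), optimizer = optimizer,
                 spokes_per_example = as.integer(spokes_per_example),
                 seed = as.integer(seed), checkpointed = checkpointed,
                 power_iter = power_iter, power_tol = power_tol),
            class = "train_config")
}

#' Build one retrospectively undersampled training example
#'
#' Draws a fresh random spoke subset from densely acquired k-space, recomputes
#' the density compensation and the spectrally normalized encoding operator
#' for the subset, and returns the gridded image as network input together
#' with the fixed supervision target.
#'
#' @param gt_kspace raw `kspace` acquired on `traj` (the dense scan)
#' @param traj the dense `radial_traj`
#' @param op_config list with `maps` (coil maps), optional `plan` (master
#'   NUFFT plan for `traj`, subset for speed), optional `target`
#'   (supervision volume), and optional `power_iter`, `power_tol`,
#'   NUFFT `oversamp`/`width`
#' @param n_spokes spokes to keep (<= dense spoke count)
#' @param seed subset seed
#' @return list: `input` (gridded volume), `target`, `op` (normalized subset
#'   operator), `kspace` (raw subset data), `spoke_idx`
#' @export
make_training_example <- function(gt_kspace, traj, op_config, n_spokes, seed) {
  sub <- subsample_spokes(gt_kspace, traj, n_spokes, seed = seed)
  plan <- if (!is.null(op_config$plan))
    subset_nufft_plan(op_config$plan, sub$sample_idx)
  else
    make_nufft_plan(sub$traj, dim(op_config$maps)[1:3],
                    oversamp = op_config$oversamp %||% 1.25,
                    width = op_config$width %||% 6)
  op <- encoding_op(op_config$maps, sub$traj, dcf = sub$dcf, plan = plan)
  # slow power-iteration convergence on small subsets only perturbs the scale
  # slightly; keep the estimate without propagating the warning per example
  op <- suppressWarnings(
    normalize_operator(op, n_iter = op_config$power_iter %||% 30,
                       tol = op_config$power_tol %||% 1e-5,
                       seed = op_config$norm_seed %||% 0))
  list(input = gridded_recon(op, sub$kspace), target = op_config$target,
       op = op, kspace = sub$kspace, spoke_idx = sub$spoke_idx)
}

#' Mean squared error between complex volumes (2-channel convention)
#'
#' Mean over all voxels and both real/imaginary channels of the squared
#' difference: `sum(|pred - target|^2) / (2 * n_voxels)`.
#'
#' @param pred,target complex 3D arrays of equal shape
#' @return non-negative scalar
#' @export
mse_loss <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch in mse_loss")
  sum(Mod(pred - target)^2) / (2 * prod(as.numeric(dim(pred))))
}

# flatten all trainable parameters (regularizer weights + step-size thetas)
model_params <- function(model) {
  c(unlist(lapply(model$regs, function(r) weights_to_vec(r$weights))),
    model$theta)
}

model_set_params <- function(model, v) {
  pos <- 0L
  for (i in seq_along(model$regs)) {
    n <- length(weights_to_vec(model$regs[[i]]$weights))
    model$regs[[i]]$weights <- vec_to_weights(v[pos + seq_len(n)],
                                              model$regs[[i]]$weights)
    pos <- pos + n
  }
  model$theta <- v[pos + seq_along(model$theta)]
  model
}

grad_vec <- function(model, fb) {
  c(unlist(lapply(fb$grads, weights_to_vec)), fb$gtheta)
}

#' Train an unrolled model
#'
#' Runs `cfg$n_iterations` of: draw a training example (cycling through the
#' dataset, with a fresh seeded spoke subset each iteration), forward +
#' backward under block-wise checkpointing, one Adam step. Fully reproducible
#' from the config seed and the model init seed. Aborts on non-finite loss.
#'
#' @param model an `unrolled_model`
#' @param dataset list of examples; each a list with `kspace` (raw dense
#'   data), `traj`, `maps`, `target`, optional `plan` (master NUFFT plan)
#' @param cfg a [train_config()]
#' @param verbose print progress every 25 iterations
#' @return list of class `train_fit`: `model` (trained), `loss_trace`,
#'   `cfg`, `example_idx`, `subset_seeds`
#' @export
train <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "unrolled_model"), length(dataset) >= 1)
  n_it <- cfg$n_iterations
  subset_seeds <- derive_seeds(cfg$seed, n_it)
  example_idx <- rep_len(seq_along(dataset), n_it)

  p <- model_params(model)
  m1 <- numeric(length(p)); m2 <- numeric(length(p))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(n_it)
  for (it in seq_len(n_it)) {
    ex <- dataset[[example_idx[it]]]
    tex <- make_training_example(
      ex$kspace, ex$traj,
      list(maps = ex$maps, plan = ex$plan, target = ex$target,
           power_iter = cfg$power_iter, power_tol = cfg$power_tol),
      n_spokes = cfg$spokes_per_example, seed = subset_seeds[it])
    fb <- model_forward_backward(model, tex$input, tex$kspace, tex$op,
                                 tex$target, checkpointed = cfg$checkpointed)
    loss_trace[it] <- fb$loss
    g <- grad_vec(model, fb)
    m1 <- b1 * m1 + (1 - b1) * g
    m2 <- b2 * m2 + (1 - b2) * g^2
    step <- cfg$learning_rate * (m1 / (1 - b1^it)) /
      (sqrt(m2 / (1 - b2^it)) + eps)
    if (cfg$learning_rate > 0) {
      p <- p - step
      model <- model_set_params(model, p)
    }
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %4d/%d  loss %.6g", it, n_it, loss_trace[it]))
  }
  structure(list(model = model, loss_trace = loss_trace, cfg = cfg,
                 example_idx = example_idx, subset_seeds = subset_seeds),
            class = "train_fit")
}
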