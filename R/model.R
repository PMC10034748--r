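# The unrolled MBDL model: per unroll, a block-wise CNN regularizer followed
# by a gradient data-consistency step with a learnable (softplus-positive)
# step size, enforced channel-by-channel. Backward passes recompute
# activations from per-unroll checkpoints (and per-patch checkpoints inside
# the regularizer).

#' Construct an unrolled MBDL model
#'
#' `n_unrolls` repetitions of (block-wise regularizer, data-consistency
#' gradient step). Regularizer weights are unshared across unrolls by default;
#' step sizes are per-unroll scalars `t_k = softplus(theta_k)` initialized at
#' 1. With `n_unrolls = 0` the model is the identity. `dc_enabled = FALSE`
#' gives the network-only variant (regularizer passes without data
#' consistency), used as the 0-unroll arm of the unroll study.
#'
#' @param n_unrolls number of unrolls N (>= 0)
#' @param volume_shape 3-vector; fixes the block scheme
#' @param splits per-axis block counts for the block scheme
#' @param cfg a [reg_config()]
#' @param dc_enabled include the data-consistency step
#' @param shared_weights share one regularizer across unrolls
#' @param halo halo width; defaults to the regularizer receptive radius
#' @param reg_init weight initialization mode, see [make_regularizer()]
#' @return object of class `unrolled_model`
#' @export
unrolled_model <- function(n_unrolls, volume_shape, splits = 2,
                           cfg = reg_config(), dc_enabled = TRUE,
                           shared_weights = FALSE, halo = NULL,
                           reg_init = "identity_out") {
  stopifnot(n_unrolls >= 0)
  n_reg <- if (shared_weights) min(1L, n_unrolls) else n_unrolls
  regs <- lapply(seq_len(max(n_reg, 0L)), function(k) {
    c2 <- cfg; c2$init_seed <- cfg$init_seed + (k - 1L) * 1000L
    make_regularizer(c2, init = reg_init)
  })
  radius <- if (length(regs)) regs[[1]]$receptive_radius else 0L
  scheme <- plan_blocks(volume_shape, splits,
                        halo = if (is.null(halo)) radius else halo)
  structure(list(n_unrolls = as.integer(n_unrolls), regs = regs,
                 theta = rep(softplus_inv(1), n_unrolls * dc_enabled),
                 scheme = scheme, cfg = cfg, dc_enabled = dc_enabled,
                 shared_weights = shared_weights),
            class = "unrolled_model")
}

#' @export
print.unrolled_model <- function(x, ...) {
  cat(sprintf("unrolled MBDL model: %d unrolls%s, %d-channel regularizer (%d res blocks), %s\n",
              x$n_unrolls, if (x$dc_enabled) "" else " (network-only, no DC)",
              x$cfg$channels, x$cfg$n_res_blocks, format(x$scheme$splits[1])))
  invisible(x)
}

reg_for_unroll <- function(model, k) {
  if (model$shared_weights) model$regs[[1]] else model$regs[[k]]
}

#' Data-consistency gradient step
#'
#' `x - t * E^H (E x - y)`, with the gradient accumulated one channel at a
#' time (channel-wise checkpointing contract: only one channel's k-space
#' working set is live at a time).
#'
#' @param x complex image volume
#' @param y `kspace` (prepared to the operator domain if raw)
#' @param op a (preferably normalized) `encoding_op`
#' @param t step size
#' @param checkpointed recorded flag; the channel-wise loop stores no
#'   per-channel intermediates either way
#' @return complex image volume
#' @export
dc_step <- function(x, y, op, t, checkpointed = TRUE) {
  y <- prepare_kspace(op, y)
  x - t * dc_gradient(x, y$samples, op)
}

# E^H(Ex - y) accumulated channel-by-channel; y is a prepared sample matrix
dc_gradient <- function(x, ysamp, op) {
  stopifnot(all(dim(x) == op$shape), nrow(ysamp) == op$n_channels)
  g <- array(0i, op$shape)
  for (c_i in seq_len(op$n_channels)) {
    s <- op$scale * op$sqrt_w * nufft_forward(op$maps[, , , c_i] * unclass(x), op$plan)
    g <- g + Conj(op$maps[, , , c_i]) *
      nufft_adjoint(op$sqrt_w * (s - ysamp[c_i, ]), op$plan) * op$scale
  }
  g
}

#' Reconstruct with the unrolled model
#'
#' Runs `x <- dc_step(regularize(x))` for each unroll starting from `x0`
#' (typically the gridded reconstruction). Deterministic given the weights.
#'
#' @param x0 complex start volume
#' @param y `kspace`
#' @param op `encoding_op` (ignored when the model has no DC step)
#' @param model an `unrolled_model`
#' @param checkpointed per-patch checkpointing flag (inference output is
#'   identical either way)
#' @return complex image volume
#' @export
unrolled_reconstruct <- function(x0, y, op, model, checkpointed = TRUE) {
  stopifnot(inherits(model, "unrolled_model"))
  if (model$n_unrolls == 0) return(x0)
  if (model$dc_enabled) {
    y <- prepare_kspace(op, y)
    tvec <- softplus(model$theta)
  }
  x <- x0
  for (k in seq_len(model$n_unrolls)) {
    x <- regularize(x, reg_for_unroll(model, k), model$scheme,
                    checkpointed = checkpointed)
    if (model$dc_enabled)
      x <- x - tvec[k] * dc_gradient(x, y$samples, op)
  }
  x
}

#' Forward and backward pass of the unrolled model under a training loss
#'
#' Computes the MSE loss of the reconstruction against `target` and the
#' gradients with respect to every regularizer weight and step-size
#' parameter. Per-unroll inputs are checkpointed; in checkpointed mode the
#' regularizer activations are recomputed patch-by-patch during the backward
#' sweep, in cached mode (`checkpointed = FALSE`) they are stored during the
#' forward pass. Both modes return identical gradients.
#'
#' @param model an `unrolled_model`
#' @param x0 start volume
#' @param y `kspace`
#' @param op `encoding_op`
#' @param target complex supervision volume
#' @param checkpointed store (FALSE) or recompute (TRUE) CNN activations
#' @return list: `loss`, `pred`, `grads` (per-unroll list of `gw`),
#'   `gtheta`, `gx0`
#' @export
model_forward_backward <- function(model, x0, y, op, target,
                                   checkpointed = TRUE) {
  N <- model$n_unrolls
  dc <- model$dc_enabled
  if (dc) {
    y <- prepare_kspace(op, y)
    tvec <- softplus(model$theta)
  }
  V <- prod(as.numeric(dim(x0)))
  xs <- vector("list", N + 1L)   # per-unroll checkpoints (N+1 volumes)
  caches <- if (!checkpointed) vector("list", N) else NULL
  zs <- if (!checkpointed) vector("list", N) else NULL
  xs[[1]] <- x0
  for (k in seq_len(N)) {
    z <- regularize(xs[[k]], reg_for_unroll(model, k), model$scheme,
                    checkpointed = checkpointed)
    if (!checkpointed) {
      caches[[k]] <- attr(z, "cache")
      attr(z, "cache") <- NULL
      zs[[k]] <- z
    }
    xs[[k + 1L]] <- if (dc) z - tvec[k] * dc_gradient(z, y$samples, op) else z
  }
  pred <- xs[[N + 1L]]
  diff <- pred - target
  loss <- sum(Mod(diff)^2) / (2 * V)
  if (!is.finite(loss)) stop("non-finite training loss")

  g <- diff / V    # dL/dRe + i dL/dIm
  n_reg <- length(model$regs)
  gws <- lapply(seq_len(n_reg), function(i) zero_like_weights(model$regs[[i]]$weights))
  gtheta <- numeric(length(model$theta))
  for (k in rev(seq_len(N))) {
    reg <- reg_for_unroll(model, k)
    gz <- if (dc) g - tvec[k] * ehe_apply(op, g) else g
    bk <- regularize_backward(xs[[k]], reg, model$scheme, gz,
                              caches = if (!checkpointed) caches[[k]] else NULL,
                              return_output = dc && checkpointed)
    if (dc) {
      # the regularizer output feeding this DC step: recomputed during the
      # checkpointed backward sweep, or stored in cached mode; the DC residual
      # follows from the stored next checkpoint without extra NUFFTs
      z <- if (checkpointed) bk$output else zs[[k]]
      r <- (z - xs[[k + 1L]]) / tvec[k]
      gtheta[k] <- -real_dot(g, r) * sigmoid(model$theta[k])
    }
    ridx <- if (model$shared_weights) 1L else k
    gws[[ridx]] <- add_weights(gws[[ridx]], bk$gw)
    g <- bk$gx
  }
  list(loss = loss, pred = pred, grads = gws, gtheta = gtheta, gx0 = g)
}
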