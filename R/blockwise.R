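# Block-wise learning core: patch decomposition with halo extension,
# recomposition with internal-edge correction (core crop), sequential
# patch-wise operator application, and the element-count memory model.
#
# The internal-edge correction is by construction exact: each patch carries a
# halo of true neighbouring voxels at least as wide as the operator's
# receptive radius, and only the patch core is written back, so the blockwise
# result equals the full-volume application identically.

#' Plan a block decomposition of a volume
#'
#' Splits each axis into `splits` contiguous cores (earlier blocks take the
#' extra voxel when the axis is not divisible), each extended by `halo` voxels
#' per side (zero-padded where the extension leaves the volume). Blocks are
#' ordered lexicographically with axis 1 varying fastest (R array order).
#'
#' @param volume_shape 3-vector (Nx, Ny, Nz)
#' @param splits per-axis block counts (scalar or 3-vector)
#' @param halo per-axis halo width in voxels (scalar or 3-vector, >= 0)
#' @return object of class `block_scheme`; fields include `n_blocks`,
#'   `n_internal_faces`, and per-block core/extended index ranges
#' @export
plan_blocks <- function(volume_shape, splits, halo = 0) {
  volume_shape <- check_shape3(volume_shape)
  splits <- as.integer(rep(splits, length.out = 3))
  halo <- as.integer(rep(halo, length.out = 3))
  if (any(splits < 1)) stop("splits must be >= 1 per axis")
  if (any(halo < 0)) stop("halo must be >= 0")
  if (any(splits > volume_shape)) stop("splits exceed the volume shape")

  ax <- vector("list", 3)
  for (a in 1:3) {
    n <- volume_shape[a]; s <- splits[a]
    sizes <- rep(n %/% s, s)
    if (n %% s > 0) sizes[seq_len(n %% s)] <- sizes[seq_len(n %% s)] + 1L
    hi <- cumsum(sizes); lo <- hi - sizes + 1L
    ax[[a]] <- data.frame(lo = lo, hi = hi, size = sizes)
  }
  grid <- expand.grid(i1 = seq_len(splits[1]), i2 = seq_len(splits[2]),
                      i3 = seq_len(splits[3]))
  blocks <- vector("list", nrow(grid))
  for (b in seq_len(nrow(grid))) {
    core <- ext <- matrix(0L, 3, 2)
    patch_shape <- integer(3); off <- integer(3)
    for (a in 1:3) {
      r <- ax[[a]][grid[b, a], ]
      core[a, ] <- c(r$lo, r$hi)
      ext[a, ] <- c(max(1L, r$lo - halo[a]), min(volume_shape[a], r$hi + halo[a]))
      patch_shape[a] <- r$size + 2L * halo[a]
      # where the clipped extended range lands inside the (possibly zero-padded) patch
      off[a] <- ext[a, 1] - (r$lo - halo[a]) + 1L
    }
    blocks[[b]] <- list(index = as.integer(grid[b, ]), core = core, ext = ext,
                        patch_shape = patch_shape, pad_offset = off)
  }
  n_internal_faces <- as.integer(sum(vapply(1:3, function(a)
    (splits[a] - 1L) * prod(splits[-a]), numeric(1))))
  structure(list(volume_shape = volume_shape, splits = splits, halo = halo,
                 n_blocks = as.integer(prod(splits)),
                 n_internal_faces = n_internal_faces,
                 blocks = blocks),
            class = "block_scheme")
}

#' @export
print.block_scheme <- function(x, ...) {
  cat(sprintf("block scheme: %s volume, %s splits (%d blocks, %d internal faces), halo %s\n",
              paste(x$volume_shape, collapse = "x"),
              paste(x$splits, collapse = "x"),
              x$n_blocks, x$n_internal_faces,
              paste(x$halo, collapse = "/")))
  invisible(x)
}

# extract one halo-extended, zero-padded patch
extract_patch1 <- function(x, blk) {
  p <- array(if (is.complex(x)) 0i else 0, blk$patch_shape)
  e <- blk$ext; o <- blk$pad_offset
  n <- e[, 2] - e[, 1] + 1L
  p[o[1]:(o[1] + n[1] - 1), o[2]:(o[2] + n[2] - 1), o[3]:(o[3] + n[3] - 1)] <-
    x[e[1, 1]:e[1, 2], e[2, 1]:e[2, 2], e[3, 1]:e[3, 2]]
  p
}

# core of a processed patch (the internal-edge correction is this crop)
patch_core <- function(p, blk, halo) {
  cs <- blk$core[, 2] - blk$core[, 1] + 1L
  p[(halo[1] + 1):(halo[1] + cs[1]),
    (halo[2] + 1):(halo[2] + cs[2]),
    (halo[3] + 1):(halo[3] + cs[3]), drop = FALSE]
}

# adjoint of extract_patch1: accumulate a patch-shaped gradient back into the
# volume over the clipped extended range
scatter_patch1 <- function(acc, p, blk) {
  e <- blk$ext; o <- blk$pad_offset
  n <- e[, 2] - e[, 1] + 1L
  acc[e[1, 1]:e[1, 2], e[2, 1]:e[2, 2], e[3, 1]:e[3, 2]] <-
    acc[e[1, 1]:e[1, 2], e[2, 1]:e[2, 2], e[3, 1]:e[3, 2]] +
    p[o[1]:(o[1] + n[1] - 1), o[2]:(o[2] + n[2] - 1), o[3]:(o[3] + n[3] - 1)]
  acc
}

#' Decompose a volume into halo-extended patches
#'
#' @param x 3D array matching `scheme$volume_shape`
#' @param scheme a `block_scheme`
#' @return list of patch arrays in block order
#' @export
extract_patches <- function(x, scheme) {
  stopifnot(inherits(scheme, "block_scheme"), all(dim(x) == scheme$volume_shape))
  lapply(scheme$blocks, function(blk) extract_patch1(x, blk))
}

#' Recompose patches into the full volume
#'
#' Each patch contributes only its core region; halo voxels are discarded.
#' This crop removes zero-padding artifacts at internal block edges exactly,
#' so `recompose(extract_patches(x)) == x` for any halo.
#'
#' @param patches list of patch arrays (block order)
#' @param scheme a `block_scheme`
#' @return 3D array of shape `scheme$volume_shape`
#' @export
recompose <- function(patches, scheme) {
  stopifnot(inherits(scheme, "block_scheme"))
  if (length(patches) != scheme$n_blocks) stop("patch count does not match the scheme")
  cplx <- is.complex(patches[[1]])
  out <- array(if (cplx) 0i else 0, scheme$volume_shape)
  for (b in seq_len(scheme$n_blocks)) {
    blk <- scheme$blocks[[b]]
    if (!all(dim(patches[[b]]) == blk$patch_shape))
      stop("patch shape does not match the scheme")
    co <- blk$core
    out[co[1, 1]:co[1, 2], co[2, 1]:co[2, 2], co[3, 1]:co[3, 2]] <-
      patch_core(patches[[b]], blk, scheme$halo)
  }
  out
}

#' Apply an image-space operator patch-by-patch
#'
#' Processes patches strictly sequentially (one patch working set live at a
#' time) and recomposes cores. When `scheme$halo` is at least the operator's
#' receptive radius the result equals the full-volume application; smaller
#' halos are refused unless `override_halo_check = TRUE` (approximate mode,
#' differences confined to within the receptive radius of internal faces).
#'
#' @param x 3D array
#' @param f the operator: either `function(patch) patch`, or a list with
#'   `$forward` and optionally `$receptive_radius` and
#'   `$activations_per_voxel` (element-count accounting)
#' @param scheme a `block_scheme`
#' @param checkpointed logical; recorded in the accounting (forward-only
#'   application stores no activations either way)
#' @param override_halo_check allow halo < receptive radius
#' @return processed volume; attribute `"memory"` reports element-count
#'   accounting (`peak_live_elements`, `volume_elements`,
#'   `max_patch_elements`)
#' @export
blockwise_apply <- function(x, f, scheme, checkpointed = FALSE,
                            override_halo_check = FALSE) {
  stopifnot(inherits(scheme, "block_scheme"), all(dim(x) == scheme$volume_shape))
  fwd <- if (is.function(f)) f else f$forward
  r <- if (is.function(f)) NULL else f$receptive_radius
  apv <- if (is.function(f)) 1 else (f$activations_per_voxel %||% 1)
  if (!is.null(r) && any(scheme$halo < r) && !override_halo_check)
    stop("scheme halo is smaller than the operator receptive radius; ",
         "pass override_halo_check = TRUE for approximate blockwise application")
  V <- prod(as.numeric(scheme$volume_shape))
  out <- array(if (is.complex(x)) 0i else 0, scheme$volume_shape)
  peak_patch <- 0
  for (b in seq_len(scheme$n_blocks)) {
    blk <- scheme$blocks[[b]]
    p <- extract_patch1(x, blk)
    p <- fwd(p)
    if (!all(dim(p) == blk$patch_shape))
      stop("operator changed the patch shape")
    peak_patch <- max(peak_patch, apv * prod(as.numeric(blk$patch_shape)))
    co <- blk$core
    out[co[1, 1]:co[1, 2], co[2, 1]:co[2, 2], co[3, 1]:co[3, 2]] <-
      patch_core(p, blk, scheme$halo)
  }
  attr(out, "memory") <- list(peak_live_elements = 2 * V + peak_patch,
                              volume_elements = V,
                              max_patch_elements = peak_patch,
                              checkpointed = checkpointed)
  out
}

#' Element-count memory model of block-wise unrolled training
#'
#' Reproduces the analytic memory scaling of block-wise learning in stored
#' elements (not bytes): the forward training pass stores `(N+1) * Mem_x`
#' volume elements (one volume per unroll boundary plus the input), the
#' backward pass additionally holds the transient per-patch CNN intermediates
#' `I_k`, and patching reduces the peak CNN intermediate storage by
#' `volume voxels / largest extended patch voxels`.
#'
#' @param volume_shape 3-vector
#' @param scheme a `block_scheme` for that volume
#' @param n_unrolls number of unrolls N (>= 0)
#' @param activations_per_voxel stored CNN intermediates per patch voxel
#' @return list with `mem_x`, `forward_volume_elements` ((N+1) Mem_x),
#'   `backward_total_elements`, `patch_intermediate_elements` (per-block I_k),
#'   `reduction_factor`
#' @export
memory_footprint <- function(volume_shape, scheme, n_unrolls,
                             activations_per_voxel = 1) {
  volume_shape <- check_shape3(volume_shape)
  stopifnot(inherits(scheme, "block_scheme"),
            all(scheme$volume_shape == volume_shape),
            n_unrolls >= 0, activations_per_voxel >= 1)
  mem_x <- prod(as.numeric(volume_shape))
  patch_vox <- vapply(scheme$blocks,
                      function(blk) prod(as.numeric(blk$patch_shape)), numeric(1))
  i_k <- activations_per_voxel * patch_vox
  list(mem_x = mem_x,
       forward_volume_elements = (n_unrolls + 1) * mem_x,
       backward_total_elements = (n_unrolls + 1) * mem_x + sum(i_k),
       patch_intermediate_elements = i_k,
       reduction_factor = mem_x / max(patch_vox))
}
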