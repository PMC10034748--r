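# Zero-padded 3D convolution (cross-correlation, torch convention). The hot
# path runs in C++ (offset-slab GEMMs, src/conv3d.cpp); a pure-R reference
# implementation is kept alongside as an independent oracle for the tests.
# Fields are 4D arrays (Nx, Ny, Nz, C); weights are 5D (kx, ky, kz, C_in,
# C_out) with odd kernel sizes.

conv3d_forward <- function(x, w) {
  d <- dim(x); kd <- dim(w)
  stopifnot(length(d) == 4, length(kd) == 5, d[4] == kd[4])
  out <- conv3d_forward_cpp(as.vector(x), as.integer(d),
                            as.vector(w), as.integer(kd))
  dim(out) <- c(d[1:3], kd[5])
  out
}

# returns grad wrt input and weights given upstream grad g (same shape as out)
conv3d_backward <- function(x, w, g) {
  d <- dim(x); kd <- dim(w)
  res <- conv3d_backward_cpp(as.vector(x), as.integer(d),
                             as.vector(w), as.integer(kd), as.vector(g))
  gx <- res$gx; dim(gx) <- d
  gw <- res$gw; dim(gw) <- kd
  list(gx = gx, gw = gw)
}

# pure-R reference (oracle) -------------------------------------------------

pad4 <- function(x, rad) {
  d <- dim(x)
  out <- array(0, c(d[1:3] + 2L * rad, d[4]))
  out[rad[1] + seq_len(d[1]), rad[2] + seq_len(d[2]), rad[3] + seq_len(d[3]), ] <- x
  out
}

conv3d_forward_ref <- function(x, w) {
  d <- dim(x); kd <- dim(w)
  rad <- (kd[1:3] - 1L) %/% 2L
  xp <- pad4(x, rad)
  nv <- prod(d[1:3])
  out <- matrix(0, nv, kd[5])
  for (o3 in seq_len(kd[3])) for (o2 in seq_len(kd[2])) for (o1 in seq_len(kd[1])) {
    src <- xp[(o1 - 1L) + seq_len(d[1]), (o2 - 1L) + seq_len(d[2]),
              (o3 - 1L) + seq_len(d[3]), , drop = FALSE]
    dim(src) <- c(nv, kd[4])
    out <- out + src %*% matrix(w[o1, o2, o3, , ], kd[4], kd[5])
  }
  dim(out) <- c(d[1:3], kd[5])
  out
}

conv3d_backward_ref <- function(x, w, g) {
  d <- dim(x); kd <- dim(w)
  rad <- (kd[1:3] - 1L) %/% 2L
  xp <- pad4(x, rad)
  nv <- prod(d[1:3])
  gm <- g; dim(gm) <- c(nv, kd[5])
  gp <- array(0, c(d[1:3] + 2L * rad, kd[4]))
  gw <- array(0, kd)
  i1 <- seq_len(d[1]); i2 <- seq_len(d[2]); i3 <- seq_len(d[3])
  for (o3 in seq_len(kd[3])) for (o2 in seq_len(kd[2])) for (o1 in seq_len(kd[1])) {
    src <- xp[(o1 - 1L) + i1, (o2 - 1L) + i2, (o3 - 1L) + i3, , drop = FALSE]
    dim(src) <- c(nv, kd[4])
    gw[o1, o2, o3, , ] <- crossprod(src, gm)
    gsrc <- tcrossprod(gm, matrix(w[o1, o2, o3, , ], kd[4], kd[5]))
    dim(gsrc) <- c(d[1:3], kd[4])
    gp[(o1 - 1L) + i1, (o2 - 1L) + i2, (o3 - 1L) + i3, ] <-
      gp[(o1 - 1L) + i1, (o2 - 1L) + i2, (o3 - 1L) + i3, , drop = FALSE] + gsrc
  }
  gx <- gp[rad[1] + i1, rad[2] + i2, rad[3] + i3, , drop = FALSE]
  dim(gx) <- d
  list(gx = gx, gw = gw)
}

leaky_relu <- function(x, slope) {
  out <- leaky_relu_cpp(as.vector(x), slope)
  dim(out) <- dim(x)
  out
}

leaky_relu_grad <- function(x, g, slope) {
  out <- leaky_relu_grad_cpp(as.vector(x), as.vector(g), slope)
  dim(out) <- dim(x)
  out
}
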