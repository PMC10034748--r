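# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# circularly shift a 3D array by s voxels along each axis
circshift3 <- function(x, s) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) ((seq_len(d[a]) - 1 - s[a]) %% d[a]) + 1)
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

fftshift3 <- function(x) circshift3(x, floor(dim(x) / 2))
ifftshift3 <- function(x) circshift3(x, -floor(dim(x) / 2))

# centered 3D DFT: X(g) = sum_r x(r) exp(-2*pi*i g.r / M), r and g centered
# (dimensions must be even for the shift pair to be exact)
cfft3 <- function(x) fftshift3(fft(ifftshift3(x)))
# adjoint (conjugate transpose) of cfft3: unnormalized inverse DFT
cfft3_adj <- function(x) fftshift3(fft(ifftshift3(x), inverse = TRUE))

# real inner product <a, b> = Re sum conj(a)*b, the 2-channel (Re/Im) dot product
real_dot <- function(a, b) sum(Re(Conj(a) * b))

cplx_norm <- function(a) sqrt(sum(Mod(a)^2))

# relative l2 error between arrays (complex or real)
rel_err <- function(a, b) {
  d <- sqrt(sum(Mod(a - b)^2))
  n <- sqrt(sum(Mod(b)^2))
  if (n == 0) d else d / n
}

check_shape3 <- function(shape) {
  if (length(shape) != 3 || any(shape < 8) || any(shape != round(shape)))
    stop("volume shape must be three integer dimensions, each >= 8")
  as.integer(shape)
}

# softplus and its inverse, used for positivity-clamped step sizes
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# derive a stream of sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
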