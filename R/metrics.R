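# Reconstruction quality metrics: PSNR and SSIM on magnitude images, their
# relative differences from the gridded baseline, and paired t-tests.

#' Peak signal-to-noise ratio (dB)
#'
#' Computed on magnitude images: `20 log10(peak / sqrt(MSE))` with the peak
#' taken from the reference volume. Zero MSE returns the documented sentinel
#' of 300 dB (kept finite so aggregates stay finite).
#'
#' @param recon,reference complex or real 3D arrays of equal shape
#' @return PSNR in dB
#' @export
psnr <- function(recon, reference) {
  if (!all(dim(recon) == dim(reference))) stop("shape mismatch in psnr")
  a <- Mod(recon); b <- Mod(reference)
  mse <- mean((a - b)^2)
  if (mse == 0) return(300)
  min(20 * log10(max(b) / sqrt(mse)), 300)
}

# valid-mode sliding box sums along one axis via cumulative sums
box_sum_axis <- function(x, w, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(x, perm)
  d <- dim(m)
  dim(m) <- c(d[1], d[2] * d[3])
  cs <- apply(m, 2, cumsum)
  n <- d[1]
  out <- cs[w:n, , drop = FALSE]
  if (n > w)
    out[2:(n - w + 1), ] <- out[2:(n - w + 1), , drop = FALSE] -
      cs[1:(n - w), , drop = FALSE]
  dim(out) <- c(n - w + 1, d[2], d[3])
  aperm(out, order(perm))
}

# sliding-window local sums over a w^3 cube (valid mode)
local_sums <- function(x, w) {
  for (a in 1:3) x <- box_sum_axis(x, w, a)
  x
}

#' Structural similarity index (3D, uniform window)
#'
#' Mean local SSIM on magnitude images over a sliding cubic window (default
#' 7^3, valid positions only), stabilizers `K1 = 0.01`, `K2 = 0.03`, dynamic
#' range = reference peak magnitude, population (1/n) moment normalization.
#' Two identical volumes give 1; an all-zero pair gives 1 by convention.
#'
#' @param recon,reference complex or real 3D arrays (each dim >= window)
#' @param window window side length (odd)
#' @param K1,K2 stabilizer constants
#' @return SSIM in \[-1, 1\]
#' @export
ssim <- function(recon, reference, window = 7, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(recon) == dim(reference))) stop("shape mismatch in ssim")
  if (any(dim(recon) < window)) stop("volume smaller than the SSIM window")
  a <- Mod(recon); b <- Mod(reference)
  L <- max(b)
  if (L == 0) return(if (max(a) == 0) 1 else 0)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  n <- as.numeric(window)^3
  mu_a <- local_sums(a, window) / n
  mu_b <- local_sums(b, window) / n
  saa <- local_sums(a * a, window) / n - mu_a^2
  sbb <- local_sums(b * b, window) / n - mu_b^2
  sab <- local_sums(a * b, window) / n - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  mean(smap)
}

#' PSNR/SSIM relative difference from the gridded baseline
#'
#' The metric of a reconstruction minus the same metric of the gridded
#' (adjoint-NUFFT) image, both evaluated against the shared proxy reference.
#' The subtraction compensates for baseline shifts that reflect scan quality
#' rather than reconstruction quality.
#'
#' @param recon reconstruction under evaluation
#' @param gridded gridded baseline volume
#' @param reference shared (proxy) reference volume
#' @return list of class `recon_metrics`: `psnr`, `ssim`, `psnr_gridded`,
#'   `ssim_gridded`, `psnr_rel`, `ssim_rel`
#' @export
relative_difference <- function(recon, gridded, reference) {
  p <- psnr(recon, reference); s <- ssim(recon, reference)
  pg <- psnr(gridded, reference); sg <- ssim(gridded, reference)
  structure(list(psnr = p, ssim = s, psnr_gridded = pg, ssim_gridded = sg,
                 psnr_rel = p - pg, ssim_rel = s - sg),
            class = "recon_metrics")
}

#' @export
print.recon_metrics <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB (gridded %.2f, rel %+.2f) | SSIM %.4f (gridded %.4f, rel %+.4f)\n",
              x$psnr, x$psnr_gridded, x$psnr_rel,
              x$ssim, x$ssim_gridded, x$ssim_rel))
  invisible(x)
}

#' Paired two-sided t-test
#'
#' Classical paired t on the elementwise differences, with p from the t
#' distribution on n - 1 degrees of freedom. Zero-variance differences are
#' flagged degenerate with p = 1 when the mean difference is 0 and p = 0
#' otherwise.
#'
#' @param a,b numeric vectors of equal length >= 2
#' @return list: `t`, `p`, `df`, `mean_diff`, `degenerate`
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0, df = n - 1,
                mean_diff = md, degenerate = TRUE))
  }
  tstat <- md / (sdd / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1), df = n - 1,
       mean_diff = md, degenerate = FALSE)
}
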