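## Separable Gaussian / Gaussian-derivative filtering with reflect padding.
## Kernels are discretely renormalized: order-0 kernels sum to one, order-1
## kernels have unit response to a unit ramp, order-2 kernels have zero mean
## and unit response to x^2/2.

gauss_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma >= 0, order %in% 0:2)
  if (sigma == 0) {
    if (order == 0L) return(1)
    stop("derivative kernels require sigma > 0")
  }
  r <- max(ceiling(4 * sigma) + order, 1L)
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    # convolution response to f(x) = x must be 1: -sum(x * k) == 1
    return(k / (-sum(x * k)))
  }
  k <- (x^2 - sigma^2) / sigma^4 * g
  k <- k - mean(k)
  k / sum(k * x^2 / 2)
}

reflect_index <- function(n, r) {
  if (r == 0) return(seq_len(n))
  if (r > n - 1) stop("filter radius exceeds image extent")
  c(seq(r, 1), seq_len(n), seq(n, n - r + 1))
}

## Convolve along dim 1 with kernel k, reflect padding; implemented as a
## banded-matrix product so BLAS does the work.
conv_dim1 <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0) return(img * k)
  n <- nrow(img)
  pimg <- img[reflect_index(n, r), , drop = FALSE]
  K <- matrix(0, n, n + 2L * r)
  kr <- rev(k)
  for (j in seq_along(k)) {
    K[cbind(seq_len(n), seq_len(n) + j - 1L)] <- kr[j]
  }
  K %*% pimg
}

conv_sep <- function(img, k1, k2) {
  if (is.complex(img)) {
    conv_sep(Re(img), k1, k2) + 1i * conv_sep(Im(img), k1, k2)
  } else {
    t(conv_dim1(t(conv_dim1(img, k1)), k2))
  }
}

## Gaussian derivative of an image at scale sigma_px (pixels), derivative
## orders (dx, dy) along dims 1 and 2; divided by spacing^order per axis so
## the result is in physical units.
gaussian_derivative <- function(img, sigma_px, dx = 0L, dy = 0L,
                                spacing = c(1, 1)) {
  spacing <- rep_len(spacing, 2L)
  out <- conv_sep(img, gauss_kernel(sigma_px, dx), gauss_kernel(sigma_px, dy))
  out / (spacing[1]^dx * spacing[2]^dy)
}

## Angular frequency grid (rad/mm) of an n-point FFT axis.
fft_omega <- function(n, spacing) {
  m <- seq_len(n) - 1L
  f <- ifelse(m <= (n - 1L) %/% 2L, m, m - n) / n # cycles per pixel
  2 * pi * f / spacing
}
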