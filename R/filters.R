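# Scale-space primitives: sampled Gaussian kernels, separable convolution
# with reflecting boundaries, difference of Gaussians, and pointwise
# gamma-normalised Hessians. All operate on plain numeric matrices [y, x].

#' Sampled Gaussian derivative kernel
#'
#' Returns a 1-D Gaussian kernel (or its first/second derivative) sampled at
#' integer offsets. The order-0 kernel is normalised to unit sum; derivative
#' kernels have their DC response removed so a flat image maps exactly to
#' zero. The support radius defaults to 6 sigma, which keeps truncation error
#' below 1e-8 of the kernel mass.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param order derivative order, 0, 1 or 2.
#' @param radius half-width of the support; default `ceiling(6 * sigma)`.
#' @return numeric vector of length `2 * radius + 1`.
#' @keywords internal
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(is.finite(sigma), sigma > 0)
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(6 * sigma)))
  u <- seq(-radius, radius)
  g <- exp(-u^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    -u / sigma^2 * g                      # antisymmetric, sums to 0 exactly
  } else if (order == 2L) {
    k <- (u^2 / sigma^4 - 1 / sigma^2) * g
    k - mean(k)                           # enforce zero response to constants
  } else {
    stop("order must be 0, 1 or 2")
  }
}

# Reflecting (edge-inclusive, period 2n) index vector of length n + 2 * r:
# for n = 4, r = 2: 2 1 | 1 2 3 4 | 4 3
reflect_index <- function(n, r) {
  p <- seq.int(1L - r, n + r)
  m <- (p - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# 1-D convolution of a matrix along rows (dim = 1, i.e. y) or columns
# (dim = 2, x) with reflecting boundary, via shift-and-add on a padded copy.
conv1d_matrix <- function(img, kernel, dim) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- dim(img)[dim]
  idx <- reflect_index(n, r)
  if (dim == 1L) {
    pad <- img[idx, , drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * pad[j:(j + nrow(img) - 1L), , drop = FALSE]
    }
  } else {
    pad <- img[, idx, drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * pad[, j:(j + ncol(img) - 1L), drop = FALSE]
    }
  }
  out
}

#' Gaussian smoothing of an image with reflecting boundaries
#'
#' Separable convolution with a sampled, unit-sum Gaussian. Used by the
#' detection and segmentation stages; boundary handling is reflection
#' (edge pixel repeated), matching the documented filter contract.
#'
#' @param img numeric matrix `[y, x]`.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same shape.
#' @export
gauss_smooth <- function(img, sigma) {
  k <- gauss_kernel(sigma, 0L)
  conv1d_matrix(conv1d_matrix(img, k, 1L), k, 2L)
}

#' Difference-of-Gaussians band-pass filter
#'
#' The adjustable DoG used for punctum detection: the image smoothed at the
#' small scale minus the image smoothed at the large scale. Responds
#' maximally to blobs of radius close to the geometric mean of the two
#' scales, annihilates constants, and is linear in the input.
#'
#' @param frame numeric matrix `[y, x]`; all pixels must be finite.
#' @param sigma_small,sigma_large Gaussian scales in px, `0 < small < large`.
#' @return response matrix of the same shape as `frame`.
#' @export
dog_filter <- function(frame, sigma_small, sigma_large) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("`frame` must be a numeric matrix")
  }
  if (!all(is.finite(frame))) {
    stop("`frame` contains non-finite pixels; clean or crop before filtering")
  }
  stopifnot(sigma_small > 0, sigma_large > sigma_small)
  gauss_smooth(frame, sigma_small) - gauss_smooth(frame, sigma_large)
}

# Evaluate a separable kernel pair at single positions by patch dot products,
# with reflecting boundary. positions: matrix [n, 2] of 1-based (y, x).
point_separable <- function(frame, positions, ky, kx) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  ny <- nrow(frame); nx <- ncol(frame)
  iy <- reflect_index(ny, ry)
  ix <- reflect_index(nx, rx)
  vapply(seq_len(nrow(positions)), function(i) {
    y <- positions[i, 1L]; x <- positions[i, 2L]
    patch <- frame[iy[y:(y + 2L * ry)], ix[x:(x + 2L * rx)], drop = FALSE]
    as.numeric(ky %*% patch %*% kx)
  }, numeric(1))
}

#' Gamma-normalised Hessian eigenvalues at image positions
#'
#' Computes the 2x2 matrix of sigma-smoothed second spatial derivatives at
#' each position (Gaussian-derivative convolution evaluated pointwise),
#' multiplies it by sigma^2 (gamma normalisation, so responses are
#' comparable across analysis scales), and returns its eigenvalues sorted
#' ascending. At a bright blob both eigenvalues are strongly negative; on a
#' bright ridge one is near zero; in flat regions both vanish.
#'
#' Positions closer than the kernel radius to the image border are evaluated
#' with reflecting boundary and flagged in the `"reflected"` attribute.
#'
#' @param frame numeric matrix `[y, x]`.
#' @param positions integer matrix `[n, 2]` of 1-based (y, x) positions.
#' @param sigma analysis scale in px.
#' @return numeric matrix `[n, 2]` with columns `lambda1 <= lambda2`;
#'   attribute `"reflected"` is a logical vector marking border evaluations.
#' @export
hessian_eigenvalues <- function(frame, positions, sigma) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  storage.mode(positions) <- "integer"
  k0 <- gauss_kernel(sigma, 0L)
  k1 <- gauss_kernel(sigma, 1L)
  k2 <- gauss_kernel(sigma, 2L)
  r <- (length(k0) - 1L) %/% 2L
  dyy <- point_separable(frame, positions, k2, k0)
  dxx <- point_separable(frame, positions, k0, k2)
  dxy <- point_separable(frame, positions, k1, k1)
  g <- sigma^2
  dyy <- dyy * g; dxx <- dxx * g; dxy <- dxy * g
  tr <- dyy + dxx
  disc <- sqrt(pmax(0, (dyy - dxx)^2 + 4 * dxy^2))
  l1 <- (tr - disc) / 2
  l2 <- (tr + disc) / 2
  out <- cbind(lambda1 = l1, lambda2 = l2)
  attr(out, "reflected") <- positions[, 1L] <= r | positions[, 2L] <= r |
    positions[, 1L] > nrow(frame) - r | positions[, 2L] > ncol(frame) - r
  out
}

# Pointwise DoG response at given positions (used for the coarse "bulk"
# scale, where a full-image convolution would be wasted on a few points).
point_dog <- function(frame, positions, sigma_small, sigma_large) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  storage.mode(positions) <- "integer"
  ks <- gauss_kernel(sigma_small, 0L)
  kl <- gauss_kernel(sigma_large, 0L)
  # evaluate both on the larger support so the two share one patch geometry
  r <- max((length(ks) - 1L) %/% 2L, (length(kl) - 1L) %/% 2L)
  pad_to <- function(k) {
    d <- r - (length(k) - 1L) %/% 2L
    if (d > 0L) c(rep(0, d), k, rep(0, d)) else k
  }
  ks <- pad_to(ks); kl <- pad_to(kl)
  point_separable(frame, positions, ks, ks) -
    point_separable(frame, positions, kl, kl)
}
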