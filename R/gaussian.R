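#' Non-truncated Gaussian filtering and local contrast
#'
#' The filter output at pixel `(i, j)` is the Gaussian-weighted mean of *all*
#' pixels of the image -- the kernel is never truncated to a finite window.
#' Because the weight `exp(-((i-k)^2 + (j-l)^2) / (2*sigma^2))` separates
#' into row and column factors, the whole filtered image is two matrix
#' products: `Nu = GL %*% F %*% GR` for the numerator and `De = GL %*% E %*%
#' GR` (E all ones) for the normalizing denominator, with
#' `GL[i,k] = exp(-(i-k)^2 / (2*sigma^2))` and similarly `GR`.  Every output
#' is a convex combination of the inputs, so it stays within
#' `[min(F), max(F)]`.  The untruncated kernel is what makes accidental
#' collisions of filtered values rare enough for strict ordering.
#'
#' @name gaussian-filter
NULL

# one-dimensional Gaussian weight matrix: W[i,k] = exp(-(i-k)^2 / (2 sigma^2))
gaussian_weight_matrix <- function(size, sigma) {
  d <- outer(seq_len(size), seq_len(size), "-")
  exp(-(d * d) / (2 * sigma^2))
}

# Symmetrized separable products. A plain `GL %*% F %*% GR` is only
# mirror/rotation covariant up to summation-order rounding, which would turn
# the filter's exact analytic ties (mirror-symmetric inputs) into spurious
# 1-ulp orderings. Averaging each product with its reflected twin makes the
# covariance exact in floating point: reflection is a permutation and the
# average is elementwise, so filtering a mirrored image gives exactly the
# mirrored filtered image.
left_mul_sym <- function(GL, X) {
  m <- nrow(X)
  (GL %*% X + (GL %*% X[m:1, , drop = FALSE])[m:1, , drop = FALSE]) / 2
}

right_mul_sym <- function(X, GR) {
  n <- ncol(X)
  (X %*% GR + (X[, n:1, drop = FALSE] %*% GR)[, n:1, drop = FALSE]) / 2
}

gaussian_filter_channel <- function(channel, GL, GR) {
  if (min(channel) == max(channel)) {
    # algebraic fixed point of the convex-combination filter: evaluate exactly
    return(matrix(as.double(channel[1L]), nrow(channel), ncol(channel)))
  }
  Nu <- right_mul_sym(left_mul_sym(GL, channel), GR)
  De <- right_mul_sym(left_mul_sym(GL, matrix(1, nrow(channel), ncol(channel))),
                      GR)
  Nu / De
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a positive number")
  }
  if (sigma > 1e8) {
    warning("sigma above 1e8: filtered values may collide in double precision, weakening the strict ordering")
  }
  sigma
}

#' Non-truncated Gaussian filter
#'
#' @param img integer matrix in `0:255` (one channel).
#' @param sigma Gaussian spatial scale in pixels (> 0); values above `1e8`
#'   trigger a warning because the filtered values approach the global mean
#'   and may collide in double precision.
#' @return numeric matrix of filtered (real-valued) pixel values.
#' @export
gaussian_filter <- function(img, sigma = 50) {
  check_sigma(sigma)
  img <- assert_image(img)
  if (!is_gray_image(img)) stop("`img` must be a single-channel matrix")
  GL <- gaussian_weight_matrix(nrow(img), sigma)
  GR <- gaussian_weight_matrix(ncol(img), sigma)
  gaussian_filter_channel(img, GL, GR)
}

#' Per-channel Gaussian filter for color images
#'
#' Applies [gaussian_filter()] independently to each RGB channel with a
#' shared `sigma`; the row/column weight matrices are built once and reused.
#'
#' @param img integer `m x n x 3` array in `0:255`.
#' @inheritParams gaussian_filter
#' @return numeric `m x n x 3` array.
#' @export
gaussian_filter_color <- function(img, sigma = 50) {
  check_sigma(sigma)
  img <- assert_image(img)
  if (!is_color_image(img)) stop("`img` must be an m x n x 3 color image")
  GL <- gaussian_weight_matrix(dim(img)[1L], sigma)
  GR <- gaussian_weight_matrix(dim(img)[2L], sigma)
  out <- array(0, dim = dim(img))
  for (k in 1:3) {
    out[, , k] <- gaussian_filter_channel(get_channel(img, k), GL, GR)
  }
  out
}

#' Local contrast
#'
#' The signed deviation `d = F - F^GF` of each pixel (or channel value) from
#' its non-truncated Gaussian-filtered counterpart.  Positive where the pixel
#' is brighter than its (global, distance-weighted) surroundings.  This is
#' the secondary sort key of the exact-specification ordering.
#'
#' @param img integer matrix or `m x n x 3` array in `0:255`.
#' @inheritParams gaussian_filter
#' @return numeric matrix/array of the same shape as `img`.
#' @export
local_contrast <- function(img, sigma = 50) {
  img <- assert_image(img)
  fgf <- if (is_color_image(img)) gaussian_filter_color(img, sigma)
         else gaussian_filter(img, sigma)
  img - fgf
}
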