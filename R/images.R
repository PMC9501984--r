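#' Image containers and index conventions
#'
#' A grayscale image is an integer matrix (`m` rows, `n` columns) with values
#' in `0:L`; an RGB color image is an integer `m x n x 3` array.  `L = 255`
#' throughout (8-bit).  Elements are addressed either by subscripts
#' `(i, j[, k])` or by a 1-based column-major linear index: `mu = (j-1)*m + i`
#' for grayscale and `eta = m*n*(k-1) + m*(j-1) + i` for color, the channel
#' being the slowest axis.  These coincide with R's native array layout.
#'
#' @name image-model
NULL

#' Maximum level of an 8-bit image
#' @keywords internal
LEVELS_8BIT <- 255L

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

is_color_image <- function(x) {
  is.array(x) && is.numeric(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L
}

# Validate that x is an integer-valued image in [0, L]; returns x with
# integer storage mode. `what` names the argument in error messages.
assert_image <- function(x, L = LEVELS_8BIT, what = "img") {
  if (!is_gray_image(x) && !is_color_image(x)) {
    stop(sprintf("`%s` must be an m x n matrix or m x n x 3 array", what))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", what))
  }
  if (!is_wholenumber(x)) {
    stop(sprintf("`%s` must be integer-valued", what))
  }
  if (min(x) < 0 || max(x) > L) {
    stop(sprintf("`%s` has values outside [0, %d]", what, L))
  }
  storage.mode(x) <- "integer"
  x
}

assert_real_image <- function(x, what = "img") {
  if (!is_gray_image(x) && !is_color_image(x)) {
    stop(sprintf("`%s` must be an m x n matrix or m x n x 3 array", what))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", what))
  }
  x
}

# drop-safe channel extraction (1 x n and m x 1 images would otherwise lose
# their matrix shape)
get_channel <- function(img, k) {
  matrix(img[, , k], dim(img)[1L], dim(img)[2L])
}

#' Encode array subscripts as a column-major linear index
#'
#' Grayscale elements map to `mu = (j-1)*m + i`; color elements to
#' `eta = m*n*(k-1) + m*(j-1) + i` with the channel varying slowest.  These
#' are the 1-based column-major conventions used for deterministic
#' tie-breaking in pixel orderings.
#'
#' @param i,j row and column subscripts (1-based, vectorized).
#' @param k channel subscript in `1:3`, or `NULL` for grayscale.
#' @param m,n image dimensions.
#' @return integer linear indices.
#' @seealso [decode_index()]
#' @export
#' @examples
#' encode_index(2, 3, m = 4, n = 5)          # 10
#' encode_index(1, 1, k = 2, m = 2, n = 3)   # 7
encode_index <- function(i, j, k = NULL, m, n) {
  if (any(i < 1 | i > m) || any(j < 1 | j > n)) {
    stop("subscripts out of range")
  }
  if (is.null(k)) {
    as.integer((j - 1L) * m + i)
  } else {
    if (any(k < 1 | k > 3)) stop("channel subscript out of range")
    as.integer(m * n * (k - 1L) + m * (j - 1L) + i)
  }
}

#' Decode a column-major linear index into subscripts
#'
#' Inverse of [encode_index()]: `(mu - 1)` is split into quotient `(j - 1)`
#' and remainder `(i - 1)` by division by `m`; for color indices the channel
#' is peeled off first.
#'
#' @param idx linear indices in `1:(m*n)` (grayscale) or `1:(3*m*n)` (color).
#' @param m,n image dimensions.
#' @param channels 1 for grayscale, 3 for color.
#' @return a data.frame with columns `i`, `j` (and `k` when `channels = 3`).
#' @export
decode_index <- function(idx, m, n, channels = 1L) {
  top <- as.double(m) * n * channels
  if (any(idx < 1 | idx > top)) stop("linear index out of range")
  idx0 <- as.integer(idx) - 1L
  if (channels == 3L) {
    k <- idx0 %/% (m * n)
    idx0 <- idx0 %% (m * n)
    j <- idx0 %/% m
    i <- idx0 %% m
    data.frame(i = i + 1L, j = j + 1L, k = k + 1L)
  } else {
    j <- idx0 %/% m
    i <- idx0 %% m
    data.frame(i = i + 1L, j = j + 1L)
  }
}
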