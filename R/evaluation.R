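# Evaluation metrics and diagnostics: RMSE, circular hue RMSE, signed
# difference images, horizontal profiles.

#' Root mean squared error between two images
#'
#' Per-element differences, channels pooled for color images.
#'
#' @param a,b images (integer or real) of identical shape.
#' @return nonnegative scalar.
#' @export
rmse <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("`a` and `b` have different shapes")
  sqrt(mean((as.double(a) - as.double(b))^2))
}

# Hexagonal HSV hue in degrees [0, 360); NA where R = G = B (achromatic).
rgb_to_hue <- function(img) {
  img <- assert_image(img)
  if (!is_color_image(img)) stop("`img` must be an m x n x 3 color image")
  r <- as.double(img[, , 1L])
  g <- as.double(img[, , 2L])
  b <- as.double(img[, , 3L])
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  ch <- mx - mn
  h <- rep(NA_real_, length(r))
  nz <- ch > 0
  ir <- nz & mx == r
  ig <- nz & !ir & mx == g
  ib <- nz & !ir & !ig
  h[ir] <- 60 * (((g[ir] - b[ir]) / ch[ir]) %% 6)
  h[ig] <- 60 * ((b[ig] - r[ig]) / ch[ig] + 2)
  h[ib] <- 60 * ((r[ib] - g[ib]) / ch[ib] + 4)
  matrix(h, dim(img)[1L], dim(img)[2L])
}

#' Circular RMSE of hue between two color images
#'
#' Hue is the hexagonal HSV angle in degrees; differences are measured on
#' the circle (`min(|dh|, 360 - |dh|)`).  Pixels where hue is undefined
#' (achromatic, R = G = B) in *either* image are excluded from the mean; it
#' is an error if no pixel has a defined hue in both.
#'
#' @param a,b color images of identical shape.
#' @return RMSE of circular hue differences, in degrees.
#' @export
hue_rmse <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("`a` and `b` have different shapes")
  ha <- rgb_to_hue(a)
  hb <- rgb_to_hue(b)
  ok <- !is.na(ha) & !is.na(hb)
  if (!any(ok)) stop("no pixel has a defined hue in both images")
  dh <- abs(ha[ok] - hb[ok])
  dh <- pmin(dh, 360 - dh)
  sqrt(mean(dh^2))
}

#' Signed difference image around neutral gray
#'
#' `clip(a - b + 127, 0, 255)`: error-free pixels show as 127, positive
#' differences brighter, negative darker.
#'
#' @param a,b grayscale images of identical shape.
#' @return integer matrix in `0:255`.
#' @export
difference_image <- function(a, b) {
  a <- assert_image(a)
  b <- assert_image(b)
  if (!is_gray_image(a) || !is_gray_image(b)) {
    stop("difference_image expects grayscale images")
  }
  if (!identical(dim(a), dim(b))) stop("`a` and `b` have different shapes")
  out <- pmin(pmax(a - b + 127L, 0L), 255L)
  matrix(as.integer(out), nrow(a), ncol(a))
}

#' Horizontal profile of an image row
#'
#' The pixel values of row `row` in column order -- the standard way to
#' visualize value fluctuation (striping) across a nominally flat region.
#'
#' @param img grayscale image.
#' @param row row index in `1:m`.
#' @return numeric vector of length `n`.
#' @export
horizontal_profile <- function(img, row) {
  if (!is_gray_image(img)) stop("`img` must be a single-channel matrix")
  if (row < 1 || row > nrow(img)) stop("`row` out of range")
  as.vector(img[row, ])
}
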