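# Synthetic test images. Every input the test suite and the examples need is
# generated here programmatically; no external image files are required.

#' Two-level step image
#'
#' A bright left region and a dark right region separated by a vertical
#' edge -- the canonical fixture for contrasting the local-contrast and
#' l1-TV orderings on flat areas.  Defaults give a 200 x 282 image with
#' values 200 (left half) and 100 (right half), 28,200 pixels each.
#'
#' @param m,n image dimensions.
#' @param bright,dark the two levels, `0 <= dark < bright <= 255`.
#' @param split number of bright columns (the edge sits after column
#'   `split`); defaults to `n %/% 2`.
#' @return integer matrix.
#' @export
make_two_level <- function(m = 200L, n = 282L, bright = 200L, dark = 100L,
                           split = n %/% 2L) {
  if (dark < 0 || bright > 255 || dark >= bright) {
    stop("levels must satisfy 0 <= dark < bright <= 255")
  }
  if (split < 1 || split >= n) stop("`split` must be in 1..(n-1)")
  cbind(matrix(as.integer(bright), m, split),
        matrix(as.integer(dark), m, n - split))
}

#' Seeded uniform-random test image
#'
#' Independent uniform levels in `0:L`; the same seed reproduces the same
#' image and the caller's RNG state is left untouched.
#'
#' @param m,n image dimensions.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @param seed RNG seed.
#' @param L maximum level.
#' @return integer matrix or `m x n x 3` array.
#' @export
make_seeded_random <- function(m, n, channels = 1L, seed, L = LEVELS_8BIT) {
  if (!channels %in% c(1L, 3L)) stop("`channels` must be 1 or 3")
  vals <- with_seed(seed,
                    sample.int(L + 1L, m * n * channels, replace = TRUE) - 1L)
  if (channels == 3L) array(vals, dim = c(m, n, 3L)) else matrix(vals, m, n)
}

#' Mirror-symmetric test image
#'
#' Random left half, right half its exact mirror.  Because the column weight
#' matrix of the Gaussian filter is symmetric, the filtered image inherits
#' the mirror symmetry exactly, guaranteeing filtered-value collisions --
#' the fixture for tie-break handling.
#'
#' @param m,n image dimensions; `n` must be even.
#' @param seed RNG seed.
#' @return integer matrix with column `j` equal to column `n + 1 - j`.
#' @export
make_mirror_symmetric <- function(m, n, seed) {
  if (n %% 2L != 0L) stop("`n` must be even")
  half <- n %/% 2L
  left <- make_seeded_random(m, half, seed = seed)
  cbind(left, left[, half:1L, drop = FALSE])
}

#' Smooth correlated-channel color image
#'
#' A low-frequency random field per channel: a shared base field plus a
#' smaller channel-specific perturbation, each a sum of a few random 2-D
#' cosines, jointly rescaled to `0:255`.  White-noise images carry no usable
#' hue structure, so hue-preservation comparisons use these smooth images
#' with correlated channels instead.
#'
#' @param m,n image dimensions.
#' @param seed RNG seed.
#' @param waves number of random cosine components per field.
#' @param channel_weight relative amplitude of the channel-specific field
#'   (0 = identical channels, achromatic).
#' @return integer `m x n x 3` array.
#' @export
make_smooth_color <- function(m, n, seed, waves = 3L, channel_weight = 0.4) {
  cosine_field <- function(m, n, waves) {
    f <- matrix(0, m, n)
    for (w in seq_len(waves)) {
      fi <- runif(1, 0.2, 1.5) / m
      fj <- runif(1, 0.2, 1.5) / n
      ph <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.5, 1)
      f <- f + amp * cos(2 * pi * (fi * outer(seq_len(m), rep(1, n)) +
                                     fj * outer(rep(1, m), seq_len(n))) + ph)
    }
    f
  }
  with_seed(seed, {
    base <- cosine_field(m, n, waves)
    chans <- lapply(1:3, function(k) base + channel_weight * cosine_field(m, n, waves))
    lo <- min(vapply(chans, min, 0))
    hi <- max(vapply(chans, max, 0))
    out <- array(0L, dim = c(m, n, 3L))
    for (k in 1:3) {
      # one shared affine map across channels, so input hue is well defined
      out[, , k] <- matrix(as.integer(round((chans[[k]] - lo) / (hi - lo) * 255)),
                           m, n)
    }
    out
  })
}
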