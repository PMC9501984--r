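#' Histograms, conventional equalization/specification, and targets
#'
#' Histograms are raw (unnormalized) integer count vectors of length `L + 1`
#' indexed by gray level `0:L`; their total is the pixel budget `m*n`
#' (grayscale) or `3*m*n` (unified color).  A *target* histogram is any
#' nonnegative count vector whose total equals the budget exactly; exact
#' specification reproduces it bin-for-bin.
#'
#' @name histograms
NULL

#' Histogram of a grayscale image
#'
#' Counts the pixels at each level `k` in `0:L`; the counts sum to `m*n`.
#'
#' @param img integer matrix in `0:L`.
#' @param L maximum level (255 for 8-bit).
#' @return integer vector of length `L + 1`; element `k + 1` is the count of
#'   level `k`.
#' @export
compute_histogram <- function(img, L = LEVELS_8BIT) {
  img <- assert_image(img, L)
  tabulate(as.vector(img) + 1L, nbins = L + 1L)
}

#' Unified color histogram
#'
#' Pools all `3*m*n` channel values of an RGB image into one histogram, so a
#' single exact specification can act on all channels jointly.
#'
#' @param img integer `m x n x 3` array in `0:L`.
#' @inheritParams compute_histogram
#' @return integer vector of length `L + 1` with total `3*m*n`.
#' @export
compute_unified_histogram <- function(img, L = LEVELS_8BIT) {
  img <- assert_image(img, L)
  if (!is_color_image(img)) stop("`img` must be an m x n x 3 color image")
  tabulate(as.vector(img) + 1L, nbins = L + 1L)
}

#' Cumulative histogram
#'
#' Running sum `H_l = sum(h_0..h_l)`, with the convention `H_{-1} = 0` used
#' by the assignment rule of exact specification.
#'
#' @param h integer count vector (length `L + 1`).
#' @return integer (or double, if counts overflow int) vector of partial sums.
#' @export
cumulative <- function(h) {
  if (anyNA(h) || any(h < 0)) stop("histogram counts must be nonnegative")
  cumsum(h)
}

# The monotone staircase map of conventional equalization, evaluated at every
# level 0..L of a histogram: round(L * (H_v - H_vmin) / (H_vmax - H_vmin)),
# where vmin/vmax are the smallest/largest levels with nonzero count.
# Returns NULL for a degenerate (single-level) histogram.
phi_he_map <- function(h, L = LEVELS_8BIT) {
  nz <- which(h > 0L)
  if (length(nz) == 0L) stop("empty histogram")
  vmin <- nz[1L] - 1L
  vmax <- nz[length(nz)] - 1L
  if (vmin == vmax) return(NULL)
  H <- cumulative(h)
  Hmin <- H[vmin + 1L]
  Hmax <- H[vmax + 1L]
  as.integer(round_half_away(L * (H - Hmin) / (Hmax - Hmin)))
}

#' Conventional (inexact) histogram equalization
#'
#' Maps each pixel value through the monotone staircase
#' `round(L * (H_f - H_fmin) / (H_fmax - H_fmin))`.  This linearizes the
#' cumulative histogram but does not equalize the histogram itself: pixels
#' sharing a value move together, so bins merge and gaps appear.
#'
#' A constant image leaves the map undefined (zero denominator); it is
#' returned unchanged with a warning.
#'
#' @inheritParams compute_histogram
#' @return equalized integer image of the same shape.
#' @seealso [equalize_exact()] for the exact counterpart.
#' @export
conventional_equalize <- function(img, L = LEVELS_8BIT) {
  img <- assert_image(img, L)
  phi <- phi_he_map(compute_histogram(img, L), L)
  if (is.null(phi)) {
    warning("constant image: equalization map undefined; returning input unchanged")
    return(img)
  }
  out <- img
  out[] <- phi[img + 1L]
  out
}

#' Conventional (inexact) histogram specification
#'
#' Composes the equalizing staircase of the input with a linearly
#' interpolated inverse of the target's staircase: for an input value `f`
#' with `s = phi(f)`, the bracketing target level `l` satisfies
#' `phihat(l-1) < s <= phihat(l)` (with `phihat(-1) = 0`), and the output is
#' `round(((phihat(l) - s) * max(l-1, 0) + (s - phihat(l-1)) * l) /
#' (phihat(l) - phihat(l-1)))`.  When the interpolation denominator is zero
#' (only possible at `s = 0` with `phihat(0) = 0`) the level `l` is assigned
#' directly.  The result's cumulative histogram tracks the target's, but the
#' histogram itself is generally not matched -- hence "inexact".
#'
#' @inheritParams compute_histogram
#' @param target integer count vector of length `L + 1` summing to `m*n`.
#' @return specified integer image of the same shape.
#' @seealso [specify_exact()] for the exact counterpart.
#' @export
conventional_specify <- function(img, target, L = LEVELS_8BIT) {
  img <- assert_image(img, L)
  target <- check_target(target, sum(dim(img)[1] * dim(img)[2]), L)
  phi <- phi_he_map(compute_histogram(img, L), L)
  phihat <- phi_he_map(target, L)
  if (is.null(phihat)) {
    # single-level target: every pixel must take that level
    lvl <- which(target > 0L) - 1L
    out <- img
    out[] <- lvl
    return(out)
  }
  if (is.null(phi)) {
    # constant input: all pixels share one staircase value s = 0
    s_all <- rep(0L, L + 1L)
  } else {
    s_all <- phi
  }
  # map each input level v (0..L) to its output level
  lut <- integer(L + 1L)
  for (v in 0:L) {
    s <- s_all[v + 1L]
    l <- which(phihat >= s)[1L] - 1L   # minimal l with phihat(l) >= s
    prev <- if (l == 0L) 0L else phihat[l]          # phihat(l-1), phihat(-1)=0
    den <- phihat[l + 1L] - prev
    lut[v + 1L] <- if (den == 0L) l else {
      as.integer(round_half_away(((phihat[l + 1L] - s) * max(l - 1L, 0L) +
                                    (s - prev) * l) / den))
    }
  }
  out <- img
  out[] <- lut[img + 1L]
  out
}

# validate a target histogram against a pixel budget
check_target <- function(target, budget, L = LEVELS_8BIT) {
  if (length(target) != L + 1L) {
    stop(sprintf("target histogram must have %d bins, got %d", L + 1L,
                 length(target)))
  }
  if (anyNA(target) || any(target < 0) || !is_wholenumber(target)) {
    stop("target histogram counts must be nonnegative integers")
  }
  if (sum(as.double(target)) != budget) {
    stop(sprintf("target histogram total (%s) must equal the pixel budget (%s)",
                 format(sum(as.double(target))), format(budget)))
  }
  as.integer(target)
}

#' Uniform target histogram with remainder distribution
#'
#' Every bin gets `floor(budget / (L + 1))`; the shortage
#' `Q = budget - (L + 1) * floor(budget / (L + 1))` is covered by adding 1 to
#' bins `0 .. Q-1`, so the total equals the budget exactly.  Feeding this
#' target to exact specification performs exact histogram equalization.
#'
#' @param budget pixel budget (`m*n`, or `3*m*n` for unified color).
#' @param L maximum level.
#' @return integer count vector of length `L + 1` summing to `budget`.
#' @export
#' @examples
#' h <- build_uniform_target(56400)
#' table(h)   # 80 bins of 221, 176 bins of 220
build_uniform_target <- function(budget, L = LEVELS_8BIT) {
  if (budget < 1) stop("budget must be at least 1")
  base <- budget %/% (L + 1L)
  Q <- budget - (L + 1L) * base
  counts <- rep.int(base, L + 1L)
  if (Q > 0L) counts[seq_len(Q)] <- counts[seq_len(Q)] + 1L
  as.integer(counts)
}

# Largest-remainder integerization of nonnegative weights to a fixed total:
# floor the scaled weights, then give the missing units to the bins with the
# largest fractional parts (ties resolved toward lower levels).
largest_remainder <- function(weights, budget) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  exact <- weights / s * budget
  counts <- floor(exact)
  rem <- exact - counts
  short <- as.integer(round(budget - sum(counts)))
  if (short > 0L) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Discretized Gaussian target histogram
#'
#' Gaussian weights `exp(-(k - mean)^2 / (2 * sd^2))` are evaluated at the
#' integer levels `0:L` and integerized to the budget by the
#' largest-remainder method, so the total is exact.
#'
#' @inheritParams build_uniform_target
#' @param mean,sd center and width of the target in level units; the
#'   defaults (127.5, 50) give a symmetric mid-gray bell.
#' @return integer count vector of length `L + 1` summing to `budget`.
#' @export
build_gaussian_target <- function(budget, L = LEVELS_8BIT, mean = 127.5,
                                  sd = 50) {
  if (budget < 1) stop("budget must be at least 1")
  if (sd <= 0) stop("sd must be positive")
  k <- 0:L
  w <- exp(-(k - mean)^2 / (2 * sd^2))
  largest_remainder(w, budget)
}

#' Rescale a histogram to a pixel budget
#'
#' Largest-remainder integerization of the counts (treated as weights) to a
#' new total; used to reuse one image's histogram as a target for an image
#' of a different size.
#'
#' @param counts nonnegative count/weight vector of length `L + 1`.
#' @param budget required total.
#' @return integer vector summing to `budget`.
#' @export
rescale_target <- function(counts, budget) {
  if (budget < 1) stop("budget must be at least 1")
  largest_remainder(counts, budget)
}

#' Load a target histogram from a text file
#'
#' Accepts either one count per line or CSV lines `level,count` covering all
#' `L + 1` levels in order.  If the file total differs from `budget`,
#' `rescale = TRUE` rescales by the largest-remainder method; otherwise the
#' mismatch is an error.
#'
#' @param path text/CSV file with `L + 1` rows.
#' @param budget required total (`m*n` or `3*m*n`).
#' @param rescale rescale counts to the budget instead of erroring.
#' @param L maximum level.
#' @return integer count vector of length `L + 1` summing to `budget`.
#' @seealso [write_target()]
#' @export
load_target <- function(path, budget, rescale = FALSE, L = LEVELS_8BIT) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = ",", header = FALSE)
  if (nrow(tab) != L + 1L) {
    stop(sprintf("target file must have %d rows, got %d", L + 1L, nrow(tab)))
  }
  if (ncol(tab) == 2L) {
    if (!identical(as.integer(tab[[1L]]), 0:L)) {
      stop("first column must be the levels 0..L in order")
    }
    counts <- tab[[2L]]
  } else if (ncol(tab) == 1L) {
    counts <- tab[[1L]]
  } else {
    stop("target file must have 1 (count) or 2 (level,count) columns")
  }
  if (anyNA(counts) || any(counts < 0) || !is_wholenumber(counts)) {
    stop("target counts must be nonnegative integers")
  }
  counts <- as.integer(counts)
  total <- sum(as.double(counts))
  if (total != budget) {
    if (!rescale) {
      stop(sprintf("target total (%s) does not match budget (%s); set rescale = TRUE",
                   format(total), format(budget)))
    }
    counts <- largest_remainder(counts, budget)
  }
  counts
}

#' Write a target histogram as `level,count` CSV
#'
#' @param target integer count vector of length `L + 1`.
#' @param path output file.
#' @param L maximum level.
#' @export
write_target <- function(target, path, L = LEVELS_8BIT) {
  if (length(target) != L + 1L) stop("target must have L + 1 bins")
  utils::write.table(data.frame(level = 0:L, count = as.integer(target)),
                     file = path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
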