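# Independent oracles and tiny binary fixtures used across the suite.

# Direct quadruple-sum Gaussian filter: the definition, evaluated literally.
# O((mn)^2); only for tiny images.
brute_gaussian_filter <- function(F, sigma) {
  m <- nrow(F)
  n <- ncol(F)
  out <- matrix(0, m, n)
  for (i in 1:m) {
    for (j in 1:n) {
      num <- 0
      den <- 0
      for (k in 1:m) {
        for (l in 1:n) {
          w <- exp(-((i - k)^2 + (j - l)^2) / (2 * sigma^2))
          num <- num + w * F[k, l]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Dense forward-difference operator built from its Kronecker definition:
# rbind(I_n %x% D_m, D_n %x% I_m) with D_k the (k-1) x k matrix of -1/+1
# forward differences.
dense_G <- function(m, n) {
  D <- function(k) {
    if (k < 2) return(matrix(0, 0, k))
    M <- matrix(0, k - 1, k)
    M[cbind(1:(k - 1), 1:(k - 1))] <- -1
    M[cbind(1:(k - 1), 2:k)] <- 1
    M
  }
  rbind(diag(n) %x% D(m), D(n) %x% diag(m))
}

# Per-group ordering oracle: Algorithm structure taken literally -- build the
# value groups, sort each by contrast (stable), concatenate.
per_group_ordering <- function(img, d) {
  f <- as.vector(img)
  dv <- as.vector(d)
  idx <- seq_along(f)
  out <- integer(0)
  for (k in sort(unique(f))) {
    grp <- idx[f == k]
    out <- c(out, grp[order(dv[grp], method = "radix")])
  }
  out
}

# A spiky multimodal target: all mass on a few levels, total exact.
build_spiky_target <- function(budget, levels = c(0L, 100L, 255L), L = 255L) {
  counts <- integer(L + 1L)
  per <- budget %/% length(levels)
  counts[levels + 1L] <- per
  counts[levels[1L] + 1L] <- counts[levels[1L] + 1L] +
    budget - per * length(levels)
  counts
}

# Tiny PNG files that png::writePNG cannot produce, stored as hex text:
# a 2x1 16-bit grayscale PNG and a 2x2 palette-indexed PNG.
write_hex_file <- function(hex, path) {
  bytes <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                   seq(2, nchar(hex), 2)), 16L))
  writeBin(bytes, path)
  path
}

png16_hex <- paste0(
  "89504e470d0a1a0a0000000d494844520000000200000001100000000081d9fc15",
  "0000000d49444154789c636060f8ff1f00030201ffe6770bae",
  "0000000049454e44ae426082")

png_palette_hex <- paste0(
  "89504e470d0a1a0a0000000d49484452000000020000000208030000004568fd16",
  "00000300504c5445",
  paste(rep(sprintf("%02x", 0:255), each = 3), collapse = ""),
  "e2b05d7d",
  "0000000e49444154789c6360606460620600001100079ea22a12",
  "0000000049454e44ae426082")
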