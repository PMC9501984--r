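test_that("a constant image orders by linear index (total tie)", {
  img <- matrix(5L, 3, 4)
  ord <- order_pixels(img, local_contrast(img, 2))
  expect_identical(ord, 1:12)
  cimg <- array(5L, dim = c(2, 3, 3))
  expect_identical(order_elements_color(cimg, local_contrast(cimg, 2)), 1:18)
})

test_that("ties in contrast are broken by column-major index", {
  img <- matrix(5L, 1, 3)
  d <- matrix(c(-0.2, 0.1, -0.2), 1, 3)
  expect_identical(order_pixels(img, d), c(1L, 3L, 2L))
})

test_that("value groups are concatenated in ascending value order", {
  tl <- make_two_level(10, 14, split = 7)
  ord <- order_pixels(tl, local_contrast(tl, 3))
  vals <- as.vector(tl)[ord]
  expect_true(all(diff(vals) >= 0))            # 100s before 200s
  expect_identical(sum(vals[1:70] == 100L), 70L)
})

test_that("the single radix sort equals the per-group construction", {
  for (seed in 1:6) {
    img <- make_seeded_random(7, 9, seed = seed)
    d <- local_contrast(img, 3)
    expect_identical(order_pixels(img, d), per_group_ordering(img, d))
  }
  # with guaranteed ties (mirror symmetry) the equivalence still holds
  img <- make_mirror_symmetric(6, 8, seed = 30)
  d <- local_contrast(img, 3)
  expect_identical(order_pixels(img, d), per_group_ordering(img, d))
})

test_that("color element ordering follows the hand-sorted 1x1 example", {
  img <- array(c(10L, 20L, 10L), dim = c(1, 1, 3))
  d <- array(c(0.3, 0.0, -0.1), dim = c(1, 1, 3))
  # level-10 elements first (B before R since -0.1 < 0.3), then level 20
  expect_identical(order_elements_color(img, d), c(3L, 1L, 2L))
})

test_that("replicating a grayscale image into 3 channels preserves relative order", {
  img <- make_seeded_random(5, 6, seed = 31)
  cimg <- array(rep(as.vector(img), 3), dim = c(5, 6, 3))
  dg <- local_contrast(img, 3)
  dc <- local_contrast(cimg, 3)
  ordg <- order_pixels(img, dg)
  ordc <- order_elements_color(cimg, dc)
  chan1 <- ordc[ordc <= 30]
  expect_identical(chan1, ordg)
})

test_that("orderings are permutations and deterministic", {
  img <- make_mirror_symmetric(6, 10, seed = 32)
  d <- local_contrast(img, 4)
  ord1 <- order_pixels(img, d)
  ord2 <- order_pixels(img, local_contrast(img, 4))
  expect_identical(ord1, ord2)
  expect_identical(sort(ord1), 1:60)
  expect_identical(sort(rank_image(ord1, 6, 10)[ord1]), 1:60)
  expect_identical(as.vector(rank_image(ord1, 6, 10))[ord1], 1:60)
})

test_that("exact specification reproduces any valid target bin-for-bin", {
  for (seed in 1:5) {
    img <- make_seeded_random(12, 11, seed = seed)
    for (target in list(build_uniform_target(132),
                        build_gaussian_target(132),
                        build_spiky_target(132))) {
      out <- specify_exact(img, target, sigma = 5)
      expect_identical(compute_histogram(out), as.integer(target))
    }
  }
})

test_that("self-specification is the identity (grayscale and color)", {
  img <- make_seeded_random(16, 13, seed = 40)
  expect_identical(specify_exact(img, compute_histogram(img)), img)
  tl <- make_two_level(8, 10, split = 5)
  expect_identical(specify_exact(tl, compute_histogram(tl)), tl)
  cimg <- make_seeded_random(9, 7, channels = 3, seed = 41)
  expect_identical(specify_exact_color(cimg, compute_unified_histogram(cimg)),
                   cimg)
})

test_that("assigned levels are nondecreasing along the ordering", {
  img <- make_seeded_random(10, 10, seed = 42)
  d <- local_contrast(img, 3)
  ord <- order_pixels(img, d)
  out <- specify_exact(img, build_gaussian_target(100), ordering = ord)
  expect_true(all(diff(as.vector(out)[ord]) >= 0))
  # monotone consistency: f_p < f_q implies p precedes q
  pos <- integer(100); pos[ord] <- 1:100
  f <- as.vector(img)
  ij <- which(outer(f, f, "<"), arr.ind = TRUE)
  expect_true(all(pos[ij[, 1]] < pos[ij[, 2]]))
})

test_that("exact equalization hits the uniform-with-remainder target", {
  img <- make_seeded_random(16, 16, seed = 43)
  out <- equalize_exact(img, 5)
  expect_true(all(compute_histogram(out) == 1L))  # 256 pixels, one per level
  tl <- make_two_level()                            # 56,400 pixels
  h <- compute_histogram(equalize_exact(tl, 50))
  expect_true(all(h[1:80] == 221L))
  expect_true(all(h[81:256] == 220L))
})

test_that("specification validates its inputs", {
  img <- make_seeded_random(4, 4, seed = 44)
  expect_error(specify_exact(img, build_uniform_target(17)), "budget")
  expect_error(specify_exact(img, build_uniform_target(16), ordering = 1:15),
               "permutation")
  expect_error(order_pixels(img, matrix(0, 3, 3)), "shapes")
})

test_that("ordering diagnostics report collisions and minimum gaps", {
  const <- matrix(8L, 4, 4)
  rep1 <- ordering_report(const, 2)
  expect_identical(rep1$min_diff, 0)
  expect_identical(rep1$tie_count, 15L)

  two <- matrix(c(0L, 255L), 1, 2)
  rep2 <- ordering_report(two, 1)
  expect_identical(rep2$tie_count, 0L)
  expect_gt(rep2$min_diff, 0)
  expect_identical(length(rep2$sorted_values), 2L)

  # mirror symmetry forces exact filtered-value collisions
  mir <- make_mirror_symmetric(4, 8, seed = 50)
  fg <- gaussian_filter(mir, 3)
  expect_identical(fg, fg[, 8:1])
  rep3 <- ordering_report(mir, 3)
  expect_gt(rep3$tie_count, 0L)
  # ordering remains a valid permutation despite the ties
  ord <- order_pixels(mir, local_contrast(mir, 3))
  expect_identical(sort(ord), 1:32)
})
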