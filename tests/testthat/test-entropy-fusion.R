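test_that("entropy filter matches the nested-loop oracle and its bounds", {
  set.seed(42)
  for (rep in 1:50) {
    x <- matrix(runif(16 * 16), 16, 16)
    em <- entropy_filter(x, 3L, 256L)
    expect_equal(em$values, brute_entropy_filter(x, 3L, 256L),
                 tolerance = 1e-14)
    expect_true(all(em$values >= 0 & em$values <= 1))
  }
  # a different window/bin setting agrees too
  x <- matrix(rnorm(12 * 9), 12, 9)
  expect_equal(entropy_filter(x, 5L, 16L)$values,
               brute_entropy_filter(x, 5L, 16L), tolerance = 1e-14)
})

test_that("entropy filter degenerate and hand-computed cases", {
  expect_true(all(entropy_filter(matrix(7, 10, 10))$values == 0))

  # interior 3x3 window with a 5/4 split of two quantized levels
  x <- matrix(0, 5, 5)
  x[3, 3] <- 1; x[2, 2] <- 1; x[2, 4] <- 1; x[4, 3] <- 1
  expected <- (-(5 / 9) * log2(5 / 9) - (4 / 9) * log2(4 / 9)) / log2(9)
  expect_equal(entropy_filter(x)$values[3, 3], expected, tolerance = 1e-12)

  expect_error(entropy_filter(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
  expect_error(entropy_filter(matrix(1, 8, 8), window_side = 4), "odd")
})

test_that("homogeneity is the exact complement of normalized entropy", {
  expect_true(all(homogeneity(matrix(0, 4, 4)) == 1))
  expect_true(all(homogeneity(matrix(1, 4, 4)) == 0))
  set.seed(1)
  v <- matrix(runif(25), 5, 5)
  expect_equal(homogeneity(v), 1 - v)
  expect_error(homogeneity(matrix(2, 3, 3)), "normalized")
})

test_that("local weighted convolution matches the nested-loop oracle", {
  set.seed(9)
  for (rep in 1:50) {
    w <- matrix(runif(64), 8, 8)
    f <- matrix(rnorm(64), 8, 8)
    expect_equal(local_weighted_convolution(w, f, 3L),
                 brute_window_mean(w, f, 3L), tolerance = 1e-14)
  }
  expect_true(all(local_weighted_convolution(matrix(0, 6, 6),
                                             matrix(rnorm(36), 6, 6)) == 0))
  # unit weight over constant NIR returns the constant away from borders
  out <- local_weighted_convolution(matrix(1, 8, 8), matrix(2.5, 8, 8))
  expect_equal(out[2:7, 2:7], matrix(2.5, 6, 6), tolerance = 1e-12)
  expect_error(local_weighted_convolution(matrix(1, 4, 4), matrix(1, 5, 5)),
               "consistency")
})

test_that("fusion rule identities hold exactly", {
  set.seed(5)
  ll <- lapply(1:3, function(i) matrix(runif(100), 10, 10))

  # vanishing NIR leaves the colour coefficients untouched
  f0 <- fuse(ll, matrix(0, 10, 10))
  for (i in 1:3) expect_identical(f0$channels[[i]], ll[[i]])

  # maximal entropy (zero homogeneity) switches the additive term off
  ones <- lapply(1:3, function(i) matrix(1, 10, 10))
  f1 <- fuse(ll, matrix(rnorm(100), 10, 10), entropy_maps = ones)
  for (i in 1:3) expect_identical(f1$channels[[i]], ll[[i]])

  # constant colour (zero entropy) + constant NIR adds c in the interior
  llc <- lapply(c(0.2, 0.5, 0.8), function(m) matrix(m, 10, 10))
  fc <- fuse(llc, matrix(0.3, 10, 10))
  for (i in 1:3) {
    expect_equal(fc$channels[[i]][3:8, 3:8],
                 llc[[i]][3:8, 3:8] + 0.3, tolerance = 1e-12)
  }
  expect_error(fuse(ll, matrix(0, 4, 4)), "consistency")
})

test_that("fused coefficients dominate the colour LL when NIR is nonnegative", {
  set.seed(14)
  for (rep in 1:20) {
    ll <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
    nir <- matrix(runif(64), 8, 8)
    fz <- fuse(ll, nir)
    for (i in 1:3) expect_true(all(fz$channels[[i]] >= ll[[i]] - 1e-12))
    # constant-NIR inputs essentially keep the per-channel contrast range:
    # the additive term is bounded by the NIR level, so any compression is
    # marginal (homogeneous regions gain slightly more than busy ones)
    fc <- fuse(ll, matrix(0.4, 8, 8))
    for (i in 1:3) {
      expect_gte(diff(range(fc$channels[[i]])),
                 0.9 * diff(range(ll[[i]])))
    }
  }
})

test_that("level selection follows the entropy-difference stopping rule", {
  expect_identical(fusion_level_from_entropies(c(0.9, 0.5, 0.49), 0.05), 3L)
  expect_identical(fusion_level_from_entropies(c(0, 0, 0), 0.05), 2L)
  expect_identical(fusion_level_from_entropies(c(0.9, 0.7, 0.5), 0.05), 3L)
  expect_identical(
    fusion_level_from_entropies(c(0.9, 0.7, 0.5, 0.3), 0.05, 4L), 4L)
  expect_error(fusion_level_from_entropies(c(0.5), 0.05, 1L),
               "configuration")

  # constant image: all detail entropies zero -> first eligible level
  pyrs <- lapply(1:3, function(i) decompose(matrix(i, 64, 64), 3))
  expect_identical(select_fusion_level(pyrs, max_levels = 3), 2L)
  expect_error(select_fusion_level(pyrs, max_levels = 1), "configuration")
})

test_that("fusion adds more NIR signal to fruit than to background", {
  # The homogeneous, NIR-bright fruit region must gain strictly more from
  # the additive term than the textured background, widening the
  # fruit/background centroid separation in colour space.
  for (s in c(77, 5, 42)) {
    sc <- generate_scene(small_scene_config(s))
    chans <- lapply(1:3, function(i) sc$pair$rgb[, , i])
    J <- 2L
    lls <- lapply(chans, function(ch) decompose(ch, J)$levels[[J]]$ll)
    nir_ll <- decompose(sc$pair$nir, J)$levels[[J]]$ll
    fz <- fuse(lls, nir_ll, bins = 32L)

    # coarse fruit/background footprints (cells fully inside either region)
    cf <- decompose(sc$truth * 1, J)$levels[[J]]$ll / 2^J > 0.99
    cb <- decompose(sc$truth * 1, J)$levels[[J]]$ll / 2^J < 0.01

    for (i in 1:3) {
      gain_f <- mean(fz$channels[[i]][cf] - lls[[i]][cf])
      gain_b <- mean(fz$channels[[i]][cb] - lls[[i]][cb])
      expect_gt(gain_f, gain_b)
    }
    ctr <- function(chs, idx) sapply(chs, function(m) mean(m[idx]))
    d_fused <- sqrt(sum((ctr(fz$channels, cf) - ctr(fz$channels, cb))^2))
    d_ll <- sqrt(sum((ctr(lls, cf) - ctr(lls, cb))^2))
    expect_gt(d_fused, d_ll)
  }
})
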