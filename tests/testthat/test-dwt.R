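test_that("db4 filter bank satisfies the orthonormality identities", {
  fb <- make_db4_filters()
  expect_equal(fb$low[1], (1 + sqrt(3)) / (4 * sqrt(2)), tolerance = 1e-14)
  expect_lt(abs(sum(fb$low) - sqrt(2)), 1e-12)
  expect_lt(abs(sum(fb$low^2) - 1), 1e-12)
  expect_lt(abs(sum(fb$low * fb$high)), 1e-12)
  # alternating flip, exact
  expect_identical(fb$high,
                   c(fb$low[4], -fb$low[3], fb$low[2], -fb$low[1]))
})

test_that("single-level analysis has the constant eigenproperty and linearity", {
  sb <- analyze_level(matrix(3.2, 12, 20))
  expect_equal(dim(sb$ll), c(6L, 10L))
  expect_true(all(abs(sb$ll - 2 * 3.2) < 1e-10))
  expect_true(all(abs(sb$lh) < 1e-10))
  expect_true(all(abs(sb$hl) < 1e-10))
  expect_true(all(abs(sb$hh) < 1e-10))

  z <- analyze_level(matrix(0, 8, 8))
  expect_true(all(z$ll == 0) && all(z$hh == 0))

  expect_error(analyze_level(matrix(1, 3, 8)), "input-size")
})

test_that("analysis/synthesis is a perfect-reconstruction pair", {
  set.seed(101)
  x <- matrix(rnorm(16 * 16), 16, 16)
  sb <- analyze_level(x)
  expect_lt(max(abs(synthesize_level(sb) - x)), 1e-8)

  # odd dimensions round-trip through the replication pad
  y <- matrix(rnorm(15 * 17), 15, 17)
  expect_lt(max(abs(synthesize_level(analyze_level(y),
                                     target_shape = dim(y)) - y)), 1e-8)

  # all-zero subbands synthesize to zero; ll-only constant synthesizes flat
  zb <- analyze_level(matrix(0, 8, 8))
  expect_true(all(synthesize_level(zb) == 0))
  cb <- analyze_level(matrix(5, 8, 8))
  cb$lh[] <- 0; cb$hl[] <- 0; cb$hh[] <- 0
  expect_lt(max(abs(synthesize_level(cb) - 5)), 1e-8)

  bad <- analyze_level(matrix(rnorm(64), 8, 8))
  expect_error(synthesize_level(bad, target_shape = c(32, 32)),
               "consistency")
})

test_that("level-1 subband energy matches the input energy", {
  set.seed(11)
  for (n in c(16, 24, 64)) {
    x <- matrix(rnorm(n * n), n, n)
    sb <- analyze_level(x)
    e <- sum(sb$ll^2) + sum(sb$lh^2) + sum(sb$hl^2) + sum(sb$hh^2)
    expect_lt(abs(e - sum(x^2)), 1e-6)
  }
})

test_that("multi-level decomposition shapes, zeroing and depth errors", {
  p <- decompose(matrix(rnorm(64 * 64), 64, 64), 3)
  expect_equal(dim(p$levels[[3]]$ll), c(8L, 8L))
  expect_equal(length(p$levels), 3L)

  # constant image: zero_highpass is a no-op
  pz <- decompose(matrix(2, 32, 32), 2, zero_highpass = TRUE)
  pn <- decompose(matrix(2, 32, 32), 2, zero_highpass = FALSE)
  expect_equal(pz$levels[[2]]$ll, pn$levels[[2]]$ll)
  expect_equal(pz$levels[[1]]$lh, pn$levels[[1]]$lh)

  # constant eigenproperty at depth: LL_j = 2^j c
  expect_true(all(abs(decompose(matrix(1.5, 64, 64), 3)$levels[[3]]$ll -
                        8 * 1.5) < 1e-8))

  expect_error(decompose(matrix(1, 16, 16), 4), "input-size")
})

test_that("reconstruct inverts decompose over many seeded shapes", {
  set.seed(2024)
  worst <- 0
  for (rep in 1:200) {
    nr <- sample(16:64, 1)
    nc <- sample(16:64, 1)
    lev <- sample(1:2, 1)
    x <- matrix(rnorm(nr * nc), nr, nc)
    err <- max(abs(reconstruct(decompose(x, lev)) - x))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-8)
})

test_that("zeroing details of a noisy image removes fine-scale energy", {
  set.seed(3)
  x <- matrix(0.5, 32, 32) + matrix(rnorm(32 * 32, 0, 0.2), 32, 32)
  p <- decompose(x, 2, zero_highpass = TRUE)
  sm <- reconstruct(p)
  expect_lt(stats::sd(sm), stats::sd(x))
})

test_that("LL-only reconstruction of a block mask lands on its footprint", {
  pyr <- decompose(matrix(0.5, 32, 32), 2)
  zero_details <- function(p) {
    for (j in seq_along(p$levels)) {
      p$levels[[j]]$lh[] <- 0
      p$levels[[j]]$hl[] <- 0
      p$levels[[j]]$hh[] <- 0
    }
    p
  }
  # single coarse cell: connected bump near the nearest-neighbour footprint
  coarse <- matrix(0, 8, 8)
  coarse[4, 5] <- 1
  p1 <- zero_details(pyr)
  p1$levels[[2]]$ll <- coarse
  sm <- reconstruct(p1)
  m <- sm >= max(sm) / 2
  nn <- matrix(0, 32, 32)
  nn[13:16, 17:20] <- 1
  expect_gt(sum(m & nn == 1) / sum(m | nn == 1), 0.45)
  cm <- colMeans(which(m, arr.ind = TRUE))
  expect_lt(max(abs(cm - c(14.5, 18.5))), 2)

  # a larger block: erosion/dilation sandwich around the NN footprint
  coarse2 <- matrix(0, 8, 8)
  coarse2[3:6, 2:5] <- 1
  p2 <- zero_details(pyr)
  p2$levels[[2]]$ll <- coarse2
  sm2 <- reconstruct(p2)
  m2 <- sm2 >= max(sm2) / 2
  nn2 <- matrix(0, 32, 32)
  nn2[9:24, 5:20] <- 1
  inner <- matrix(0, 32, 32)
  inner[12:21, 8:17] <- 1  # footprint eroded by 3 px
  outer <- matrix(0, 32, 32)
  outer[6:27, 2:23] <- 1   # footprint dilated by 3 px
  expect_true(all(m2[inner == 1]))
  expect_true(all(!m2[outer == 0]))

  # zero pyramid reconstructs to zero
  p0 <- zero_details(pyr)
  p0$levels[[2]]$ll <- matrix(0, 8, 8)
  expect_true(all(reconstruct(p0) == 0))
})
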