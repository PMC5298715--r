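two_blob_image <- function() {
  ch <- function(a, b) cbind(matrix(a, 8, 4), matrix(b, 8, 4))
  list(ch(0.9, 0.2), ch(0.5, 0.6), ch(0.1, 0.3))
}

test_that("c-means recovers well-separated constant blobs exactly", {
  m <- c_means(two_blob_image(), k = 2, seed = 1)
  ctr <- m$centroids[order(m$centroids[, 1]), ]
  expect_equal(ctr[1, ], c(0.2, 0.6, 0.3), tolerance = 1e-6)
  expect_equal(ctr[2, ], c(0.9, 0.5, 0.1), tolerance = 1e-6)
  expect_identical(dim(m$labels), c(8L, 8L))
  expect_equal(length(unique(as.vector(m$labels))), 2L)
})

test_that("k = 1 returns the mean colour and seeds give determinism", {
  set.seed(99)
  img <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  m1 <- c_means(img, k = 1, seed = 7)
  expect_equal(as.vector(m1$centroids),
               sapply(img, mean), tolerance = 1e-8)

  ma <- c_means(img, k = 3, seed = 5)
  mb <- c_means(img, k = 3, seed = 5)
  expect_identical(ma$labels, mb$labels)
  expect_identical(ma$centroids, mb$centroids)

  expect_error(c_means(lapply(1:3, function(i) matrix(1, 4, 4)), k = 2),
               "configuration")
})

test_that("converged centroids are the means of their members", {
  set.seed(8)
  img <- lapply(1:3, function(i) matrix(runif(144), 12, 12))
  m <- c_means(img, k = 4, seed = 2, max_iter = 200)
  px <- do.call(cbind, lapply(img, as.vector))
  for (i in seq_len(m$k)) {
    members <- as.vector(m$labels) == i
    if (any(members)) {
      expect_equal(m$centroids[i, ],
                   colMeans(px[members, , drop = FALSE]), tolerance = 1e-6)
    }
  }
})

test_that("c-means agrees with the reference k-means on separated blobs", {
  # independent cross-check against stats::kmeans
  set.seed(123)
  px <- rbind(
    matrix(rnorm(300, 0, 0.01), 100, 3) +
      matrix(c(0.9, 0.5, 0.1), 100, 3, byrow = TRUE),
    matrix(rnorm(300, 0, 0.01), 100, 3) +
      matrix(c(0.2, 0.6, 0.3), 100, 3, byrow = TRUE)
  )
  m <- c_means(px, k = 2, seed = 3)
  km <- stats::kmeans(px, centers = 2, nstart = 5)
  a <- m$centroids[order(m$centroids[, 1]), ]
  b <- km$centers[order(km$centers[, 1]), ]
  expect_equal(unname(a), unname(b), tolerance = 1e-6)
})

test_that("fruit-cluster selection maximizes centroid R - B with tie rules", {
  mk <- function(ctr) structure(list(k = nrow(ctr), centroids = ctr),
                                class = "cluster_model")
  expect_identical(select_fruit_cluster(
    mk(rbind(c(0.9, 0.5, 0.1), c(0.2, 0.6, 0.3)))), 1L)
  expect_identical(select_fruit_cluster(
    mk(rbind(c(0.2, 0.6, 0.3), c(0.9, 0.5, 0.1)))), 2L)
  # identical centroids: lowest index
  expect_identical(select_fruit_cluster(
    mk(rbind(c(0.5, 0.5, 0.2), c(0.5, 0.5, 0.2)))), 1L)
  # equal R - B (exactly representable), larger R wins
  expect_identical(select_fruit_cluster(
    mk(rbind(c(0.5, 0.1, 0.25), c(0.75, 0.1, 0.5)))), 2L)
  expect_identical(select_fruit_cluster(mk(rbind(c(0.4, 0.2, 0.3)))), 1L)
})

test_that("coarse masks reconstruct to full resolution with the right extremes", {
  pyr <- decompose(matrix(0.4, 32, 32), 2)
  all1 <- mask_to_full_resolution(matrix(1, 8, 8), pyr)
  expect_true(all(all1 == 1))
  all0 <- mask_to_full_resolution(matrix(0, 8, 8), pyr)
  expect_true(all(all0 == 0))
  expect_equal(dim(all1), c(32L, 32L))

  coarse <- matrix(0, 8, 8)
  coarse[4, 5] <- 1
  m <- mask_to_full_resolution(coarse, pyr)
  nn <- matrix(0, 32, 32)
  nn[13:16, 17:20] <- 1
  expect_gt(mask_overlap(m, nn), 0.45)

  expect_error(mask_to_full_resolution(matrix(1, 4, 4), pyr), "consistency")
})

test_that("fruit cluster of a clean scene recovers the fruit disks", {
  # clustering isolated from the fusion term: uniform fruit brightness,
  # negligible noise, NIR ~ 0 so the fused image equals the colour LL exactly
  for (s in c(5, 17, 29)) {
    cfg <- scene_config(
      n_fruits = 3, fruit_radius_range = c(40, 52), speckle_density = 0,
      fruit_color_std = c(2e-3, 2e-3, 4e-3), nir_fruit_std = 1e-3,
      leaf_color_std = c(0, 0, 0), illumination_gradient = 0,
      nir_fruit_mean = 0, nir_bg_mean = 0, nir_bg_std = 0,
      fruit_brightness_range = c(1, 1), seed = s
    )
    sc <- generate_scene(cfg)
    chans <- lapply(1:3, function(i) sc$pair$rgb[, , i])
    pyrs <- lapply(chans, decompose, levels = 1)
    nir_ll <- decompose(sc$pair$nir, 1)$levels[[1]]$ll
    fz <- fuse(lapply(pyrs, function(p) p$levels[[1]]$ll), nir_ll,
               bins = 32L, level = 1L)
    m <- c_means(fz, k = 3, seed = 1)
    m$fruit_cluster <- select_fruit_cluster(m)
    mask <- mask_to_full_resolution(m, pyrs[[1]])
    tp <- sum(mask > 0.5 & sc$truth > 0.5)
    fn <- sum(mask <= 0.5 & sc$truth > 0.5)
    fp <- sum(mask > 0.5 & sc$truth <= 0.5)
    expect_gte(tp / (tp + fn), 0.95)
    expect_lte(fp / sum(sc$truth <= 0.5), 0.02)
  }
})
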