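#' Seeded C-means (hard k-means) clustering of a fused coefficient image
#'
#' Lloyd-style iteration on per-pixel colour 3-vectors with the Euclidean
#' metric. Initialization is deterministic for a fixed seed: the first
#' centroid is a seeded random pixel and the remaining ones are chosen by
#' farthest-point seeding (each new centroid is the pixel farthest from its
#' nearest already-chosen centroid, first index on ties). Iteration stops
#' when the largest centroid movement falls below `tol` or after `max_iter`
#' sweeps. A cluster emptied during iteration is re-seeded from the point
#' farthest from its nearest centroid (recorded in the `reseeded` count).
#'
#' @param x A `fused_image`, an H x W x C array, a list of channel matrices,
#'   or an N x d numeric matrix of feature vectors.
#' @param k Number of clusters (>= 1, and at most the number of distinct
#'   pixel vectors).
#' @param seed Integer seed making the run reproducible.
#' @param max_iter Maximum Lloyd sweeps.
#' @param tol Centroid-movement stopping tolerance (Euclidean).
#' @return An object of class `cluster_model`: `k`, `centroids` (k x d),
#'   `labels` (integer matrix over the coarse grid, values 1..k, or a vector
#'   when `x` was a plain matrix), `fruit_cluster` (NA until
#'   [select_fruit_cluster()] is applied), `iterations`, `reseeded`, `shape`.
#' @export
c_means <- function(x, k = 4L, seed = 1L, max_iter = 100L, tol = 1e-8) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)

  shape <- NULL
  if (inherits(x, "fused_image")) x <- x$channels
  if (is.list(x) || (is.array(x) && length(dim(x)) == 3)) {
    chans <- as_channel_list(x)
    shape <- dim(chans[[1]])
    px <- do.call(cbind, lapply(chans, as.vector))
  } else if (is.matrix(x)) {
    px <- x
  } else {
    stop("`x` must be a fused image, channel array/list, or N x d matrix",
         call. = FALSE)
  }
  if (!all(is.finite(px))) stop("non-finite pixel values", call. = FALSE)
  n <- nrow(px)
  if (nrow(unique(px)) < k) {
    stop("configuration error: `k` exceeds the number of distinct pixels",
         call. = FALSE)
  }

  dist2_to <- function(centroid) {
    rowSums((px - matrix(centroid, n, ncol(px), byrow = TRUE))^2)
  }

  res <- with_preserved_rng(seed, {
    centroids <- matrix(0, k, ncol(px))
    centroids[1L, ] <- px[sample.int(n, 1L), ]
    if (k > 1L) {
      mind2 <- dist2_to(centroids[1L, ])
      for (i in 2:k) {
        centroids[i, ] <- px[which.max(mind2), ]
        mind2 <- pmin(mind2, dist2_to(centroids[i, ]))
      }
    }

    labels <- integer(n)
    iterations <- 0L
    reseeded <- 0L
    for (it in seq_len(max_iter)) {
      iterations <- it
      d2 <- vapply(seq_len(k), function(i) dist2_to(centroids[i, ]),
                   numeric(n))
      if (k == 1L) d2 <- matrix(d2, ncol = 1L)
      labels <- max.col(-d2, ties.method = "first")
      newc <- centroids
      mind2 <- d2[cbind(seq_len(n), labels)]
      for (i in seq_len(k)) {
        members <- labels == i
        if (any(members)) {
          newc[i, ] <- colMeans(px[members, , drop = FALSE])
        } else {
          newc[i, ] <- px[which.max(mind2), ]
          reseeded <- reseeded + 1L
        }
      }
      move <- sqrt(max(rowSums((newc - centroids)^2)))
      centroids <- newc
      if (move < tol) break
    }
    # final assignment consistent with converged centroids
    d2 <- vapply(seq_len(k), function(i) dist2_to(centroids[i, ]), numeric(n))
    if (k == 1L) d2 <- matrix(d2, ncol = 1L)
    labels <- max.col(-d2, ties.method = "first")
    list(centroids = centroids, labels = labels, iterations = iterations,
         reseeded = reseeded)
  })

  labels <- res$labels
  if (!is.null(shape)) labels <- matrix(labels, shape[1], shape[2])
  structure(list(
    k = k, centroids = res$centroids, labels = labels,
    fruit_cluster = NA_integer_, iterations = res$iterations,
    reseeded = res$reseeded, shape = shape, seed = as.integer(seed)
  ), class = "cluster_model")
}

#' Pick the fruit cluster from a converged model
#'
#' Returns the index of the centroid maximizing the citrus colour contrast
#' `R - B` (the first vegetation index evaluated in the comparison study).
#' Ties are broken by the larger R component, then the lowest index, so the
#' choice is deterministic.
#'
#' @param model A `cluster_model` with 3-D (R, G, B) centroids.
#' @return Integer cluster index in `1:k`.
#' @export
select_fruit_cluster <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  ctr <- model$centroids
  if (ncol(ctr) < 3L) {
    stop("centroids must have at least 3 (R, G, B) components", call. = FALSE)
  }
  score <- ctr[, 1] - ctr[, 3]
  cand <- which(score == max(score))
  if (length(cand) > 1L) {
    cand <- cand[ctr[cand, 1] == max(ctr[cand, 1])]
  }
  cand[1L]
}

#' Reconstruct a coarse fruit mask to full resolution
#'
#' The binary coarse mask (1 on the fruit cluster) is placed as the deepest
#' LL coefficient of a pyramid whose detail subbands are all zero, the
#' pyramid is synthesized outward, the result is compensated for the
#' \eqn{2^{-J}} amplitude a level-J LL acquires at full resolution, and
#' binarized at `threshold`. An all-ones coarse mask therefore maps to an
#' all-ones full-resolution mask.
#'
#' @param model A `cluster_model` with `fruit_cluster` set (or, directly, a
#'   binary coarse matrix).
#' @param pyramid_meta A `dwt_pyramid` of the same image supplying per-level
#'   shapes; its depth defines J and its deepest LL shape must match the
#'   coarse mask.
#' @param threshold Binarization threshold on the rescaled smooth map
#'   (default 0.5).
#' @return Binary (0/1) numeric matrix of the pyramid's original shape, with
#'   attribute `provenance`.
#' @export
mask_to_full_resolution <- function(model, pyramid_meta, threshold = 0.5) {
  if (!inherits(pyramid_meta, "dwt_pyramid")) {
    stop("`pyramid_meta` must be a dwt_pyramid", call. = FALSE)
  }
  if (inherits(model, "cluster_model")) {
    if (is.na(model$fruit_cluster)) {
      stop("run select_fruit_cluster() first (fruit_cluster is NA)",
           call. = FALSE)
    }
    if (!is.matrix(model$labels)) {
      stop("cluster labels carry no spatial shape", call. = FALSE)
    }
    coarse <- (model$labels == model$fruit_cluster) * 1
  } else {
    coarse <- model * 1
    check_matrix(coarse)
  }
  J <- length(pyramid_meta$levels)
  deep <- pyramid_meta$levels[[J]]
  if (!identical(dim(coarse), dim(deep$ll))) {
    stop("consistency error: coarse mask shape does not match the deepest LL",
         call. = FALSE)
  }
  pyr <- pyramid_meta
  for (j in seq_len(J)) {
    pyr$levels[[j]]$lh[] <- 0
    pyr$levels[[j]]$hl[] <- 0
    pyr$levels[[j]]$hh[] <- 0
  }
  pyr$levels[[J]]$ll <- coarse
  smooth <- reconstruct(pyr) * 2^J
  mask <- (smooth >= threshold) * 1
  attr(mask, "provenance") <- "nonlinear-fusion"
  mask
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "<cluster_model> k=%d iterations=%d reseeded=%d fruit_cluster=%s\n",
    x$k, x$iterations, x$reseeded, x$fruit_cluster
  ))
  print(round(x$centroids, 4))
  invisible(x)
}
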