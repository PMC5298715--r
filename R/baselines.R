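#' Named vegetation-index projection coefficients
#'
#' @param name `"R-B"` or `"2R-G-B"`.
#' @return A `linear_method_spec`: list with `name`, `direction`, `use_dwt`.
#' @export
index_spec <- function(name = c("R-B", "2R-G-B")) {
  name <- match.arg(name)
  direction <- switch(name, "R-B" = c(1, 0, -1), "2R-G-B" = c(2, -1, -1))
  structure(list(name = name, direction = direction, use_dwt = FALSE),
            class = "linear_method_spec")
}

#' Project channels onto a linear direction
#'
#' Computes the per-pixel scalar projection `w . x` for a vegetation colour
#' index (R-B, 2R-G-B) or a fitted PCA/FLDA direction.
#'
#' @param channels H x W x C array or list of C matrices (C = 3 or 4).
#' @param spec A `linear_method_spec`, or a name accepted by [index_spec()].
#' @return Numeric matrix of projections.
#' @export
project_index <- function(channels, spec) {
  if (is.character(spec)) spec <- index_spec(spec)
  chans <- as_channel_list(channels)
  d <- spec$direction
  if (length(d) != length(chans)) {
    stop(sprintf(
      "configuration error: direction has %d coefficients but image has %d channels",
      length(d), length(chans)
    ), call. = FALSE)
  }
  Reduce(`+`, Map(function(ch, w) w * ch, chans, d))
}

#' Leading principal-component direction of a pixel cloud
#'
#' Unit leading eigenvector of the centred covariance matrix of the pixel
#' vectors (3-channel RGB or 4-channel RGB+NIR). The sign is fixed so that
#' the largest-magnitude component is positive, making fits reproducible.
#'
#' @param pixels N x d numeric matrix, N > d.
#' @param include_nir Label only: marks the spec as the 4-channel variant.
#' @return A `linear_method_spec` with unit-norm `direction`.
#' @export
fit_pca_direction <- function(pixels, include_nir = (ncol(pixels) == 4L)) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("non-finite pixels", call. = FALSE)
  if (nrow(pixels) <= ncol(pixels)) {
    stop("need more pixels than channels", call. = FALSE)
  }
  cv <- stats::cov(pixels)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 1e-12 * max(1, mean(diag(cv)))) {
    stop("data error: degenerate pixel cloud (no variance)", call. = FALSE)
  }
  w <- eg$vectors[, 1]
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  structure(list(
    name = if (include_nir) "PCA-RGBN" else "PCA-RGB",
    direction = w, use_dwt = FALSE
  ), class = "linear_method_spec")
}

#' Fisher linear discriminant direction for fruit vs background pixels
#'
#' Closed-form two-class FLDA: the direction is proportional to
#' \eqn{S_w^{-1}(\mu_{fg}-\mu_{bg})}, with the pooled within-class scatter
#' regularized by `reg * mean(diag(S_w)) * I` if it is not invertible.
#' Classification assigns a pixel to the class whose projected centroid is
#' nearer, so the fitted spec also stores the two projected class centroids.
#'
#' @param fg_pixels,bg_pixels N1 x 3 and N2 x 3 matrices of training pixels
#'   (fruit foreground and background).
#' @param reg Relative ridge used when the scatter is singular.
#' @return A `linear_method_spec` with unit `direction` and projected
#'   centroids `proj_fg`, `proj_bg`.
#' @export
fit_flda_direction <- function(fg_pixels, bg_pixels, reg = 1e-8) {
  stopifnot(is.matrix(fg_pixels), is.matrix(bg_pixels),
            ncol(fg_pixels) == ncol(bg_pixels))
  if (nrow(fg_pixels) < 1L || nrow(bg_pixels) < 1L) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  mu1 <- colMeans(fg_pixels)
  mu0 <- colMeans(bg_pixels)
  diffmu <- mu1 - mu0
  if (sqrt(sum(diffmu^2)) < 1e-12) {
    stop("data error: identical class means, no separating direction",
         call. = FALSE)
  }
  sw <- crossprod(sweep(fg_pixels, 2, mu1)) +
    crossprod(sweep(bg_pixels, 2, mu0))
  w <- tryCatch(solve(sw, diffmu), error = function(e) NULL)
  if (is.null(w)) {
    ridge <- reg * max(mean(diag(sw)), 1e-12)
    sw2 <- sw + diag(ridge, ncol(sw))
    w <- tryCatch(solve(sw2, diffmu), error = function(e) NULL)
    if (is.null(w)) {
      stop("data error: within-class scatter singular after regularization",
           call. = FALSE)
    }
  }
  w <- w / sqrt(sum(w^2))
  if (sum(w * diffmu) < 0) w <- -w  # fruit projects high
  structure(list(
    name = "FLDA", direction = w, use_dwt = FALSE,
    proj_fg = sum(w * mu1), proj_bg = sum(w * mu0)
  ), class = "linear_method_spec")
}

#' Classify pixels by the nearer projected FLDA class centroid
#'
#' @param channels H x W x 3 array or list of matrices.
#' @param spec A fitted FLDA `linear_method_spec`.
#' @return Binary (0/1) mask matrix; 1 where the projection is nearer the
#'   fruit centroid.
#' @export
flda_classify <- function(channels, spec) {
  stopifnot(!is.null(spec$proj_fg), !is.null(spec$proj_bg))
  proj <- project_index(channels, spec)
  mask <- (abs(proj - spec$proj_fg) < abs(proj - spec$proj_bg)) * 1
  attr(mask, "provenance") <- "FLDA"
  mask
}

#' Otsu optimal threshold segmentation of a scalar projection
#'
#' Quantizes the projection into a 256-bin histogram over its min--max range
#' and picks the cut maximizing the between-class variance (exhaustive scan
#' over the 255 candidate cuts, lowest cut on ties). Foreground is the
#' above-threshold class, i.e. the class with the higher mean projection.
#'
#' @param projection Non-constant numeric matrix.
#' @param bins Histogram resolution (default 256).
#' @return Binary (0/1) mask matrix with attribute `threshold` (the cut value
#'   in projection units).
#' @export
optimal_threshold <- function(projection, bins = 256L) {
  check_matrix(projection)
  rng <- range(projection)
  if (rng[1] == rng[2]) {
    stop("degenerate-data error: constant projection cannot be thresholded",
         call. = FALSE)
  }
  bins <- as.integer(bins)
  q <- quantize_levels(projection, rng[1], rng[2], bins)
  p <- tabulate(as.vector(q) + 1L, nbins = bins) / length(q)
  lev <- 0:(bins - 1L)
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[bins]
  w0 <- omega[1:(bins - 1L)]
  m0 <- mu[1:(bins - 1L)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  t_cut <- which.max(sigma_b) - 1L  # threshold between bin t_cut and t_cut+1
  mask <- (q > t_cut) * 1
  attr(mask, "threshold") <- rng[1] + (t_cut + 1) * (rng[2] - rng[1]) / bins
  attr(mask, "provenance") <- "otsu"
  mask
}
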