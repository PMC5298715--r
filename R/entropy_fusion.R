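#' Local (sliding-window) entropy filter
#'
#' For every pixel, the values in the centred `window_side` x `window_side`
#' neighbourhood are quantized into `bins` levels spanning the whole array's
#' min--max range, the window histogram is formed, and the Shannon entropy of
#' its probabilities is computed in bits and normalized by
#' `log2(window_side^2)` so the result lies in \[0, 1\]. Pixels outside the
#' array contribute through zero padding (the value 0, quantized on the same
#' global scale, clamped into range). A constant array yields an all-zero map.
#'
#' Low values mark homogeneous neighbourhoods; the fusion rule uses
#' `1 - entropy` as a homogeneity weight.
#'
#' @param coeff Numeric matrix (e.g. an LL coefficient map).
#' @param window_side Odd window side, >= 3 (default 3, the method's standard
#'   operating point).
#' @param bins Histogram resolution for the probability estimate (>= 2).
#' @return An object of class `entropy_map`: list with matrix `values` in
#'   \[0,1\], `window_side` and `bins`.
#' @export
entropy_filter <- function(coeff, window_side = 3L, bins = 256L) {
  check_matrix(coeff)
  window_side <- as.integer(window_side)
  bins <- as.integer(bins)
  if (window_side < 3L || window_side %% 2L == 0L) {
    stop("`window_side` must be an odd integer >= 3", call. = FALSE)
  }
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)

  nr <- nrow(coeff)
  nc <- ncol(coeff)
  rng <- range(coeff)
  out <- matrix(0, nr, nc)
  if (rng[1] == rng[2]) {
    return(structure(list(values = out, window_side = window_side,
                          bins = bins), class = "entropy_map"))
  }

  q <- quantize_levels(coeff, rng[1], rng[2], bins)
  qpad <- quantize_levels(0, rng[1], rng[2], bins)
  h <- (window_side - 1L) %/% 2L

  # Padded symbol field; gather the window stack by shifted blocks.
  qp <- matrix(qpad, nr + 2L * h, nc + 2L * h)
  qp[(h + 1L):(h + nr), (h + 1L):(h + nc)] <- q
  w2 <- window_side^2
  syms <- matrix(0L, nr * nc, w2)
  col <- 0L
  for (dj in -h:h) {
    for (di in -h:h) {
      col <- col + 1L
      syms[, col] <- as.vector(
        qp[(h + 1L + di):(h + nr + di), (h + 1L + dj):(h + nc + dj)]
      )
    }
  }

  norm <- log2(w2)
  ent <- apply(syms, 1L, function(v) {
    counts <- tabulate(v + 1L, nbins = bins)
    p <- counts[counts > 0L] / w2
    -sum(p * log2(p))
  })
  out[] <- ent / norm
  structure(list(values = out, window_side = window_side, bins = bins),
            class = "entropy_map")
}

#' Homogeneity weight from an entropy map
#'
#' The elementwise complement `1 - entropy` — the bracketed mask
#' "all-ones minus filtered entropy" of the fusion rule. Equals 1 exactly
#' where the neighbourhood is constant.
#'
#' @param entropy An `entropy_map` (or a numeric matrix of normalized
#'   entropies).
#' @return Numeric matrix of weights in \[0, 1\].
#' @export
homogeneity <- function(entropy) {
  v <- if (inherits(entropy, "entropy_map")) entropy$values else entropy
  check_matrix(v)
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("entropy map must be normalized to [0, 1]", call. = FALSE)
  }
  1 - v
}

#' Locally weighted convolution of a homogeneity mask with NIR coefficients
#'
#' At each pixel, the mean over the centred `window_side` window of the
#' elementwise (Hadamard) product `weight * nir_ll`, with zero padding at the
#' borders — a box mean of the product, normalized by the window pixel count
#' (9 for the default 3x3 mask). This realizes the sliding-window convolution
#' of the fusion rule's second term.
#'
#' @param weight Homogeneity weight matrix.
#' @param nir_ll NIR approximation coefficients, same shape as `weight`.
#' @param window_side Odd window side, >= 3.
#' @return Numeric matrix, same shape as the inputs.
#' @export
local_weighted_convolution <- function(weight, nir_ll, window_side = 3L) {
  check_matrix(weight)
  check_matrix(nir_ll)
  if (!identical(dim(weight), dim(nir_ll))) {
    stop("consistency error: `weight` and `nir_ll` differ in shape",
         call. = FALSE)
  }
  window_side <- as.integer(window_side)
  if (window_side < 3L || window_side %% 2L == 0L) {
    stop("`window_side` must be an odd integer >= 3", call. = FALSE)
  }
  nr <- nrow(weight)
  nc <- ncol(weight)
  h <- (window_side - 1L) %/% 2L
  prod <- weight * nir_ll
  pp <- matrix(0, nr + 2L * h, nc + 2L * h)
  pp[(h + 1L):(h + nr), (h + 1L):(h + nc)] <- prod
  acc <- matrix(0, nr, nc)
  for (dj in -h:h) {
    for (di in -h:h) {
      acc <- acc + pp[(h + 1L + di):(h + nr + di), (h + 1L + dj):(h + nc + dj)]
    }
  }
  acc / window_side^2
}

#' Entropy-gated fusion of colour and NIR approximation coefficients
#'
#' Per colour channel X, the fused coefficient is
#' \deqn{C'_X = LL_X + \mathrm{boxmean}\big[(1 - E(LL_X)) \odot LL_{NIR}\big],}
#' where \eqn{E} is the per-channel normalized local entropy
#' ([entropy_filter()]) and the box mean is [local_weighted_convolution()].
#' Homogeneous colour regions (entropy near 0) receive the full NIR
#' contribution; busy regions (entropy near 1) are left untouched, so the
#' colour contrast is preserved while homogeneous fruit regions are lifted by
#' the bright, homogeneous NIR signal.
#'
#' @param rgb_ll Three approximation-coefficient matrices (list of 3 or an
#'   H x W x 3 array), all the same shape as `nir_ll`.
#' @param nir_ll NIR approximation coefficients.
#' @param window_side,bins Entropy-filter parameters.
#' @param entropy_maps Optional list of three precomputed entropy maps
#'   (matrices or `entropy_map`s), e.g. cached from an earlier call.
#' @param level Decomposition level the coefficients came from (metadata).
#' @return An object of class `fused_image`: list with `channels` (list of
#'   three matrices), `level`, `window_side`, `bins`.
#' @export
fuse <- function(rgb_ll, nir_ll, window_side = 3L, bins = 256L,
                 entropy_maps = NULL, level = NA_integer_) {
  chans <- as_channel_list(rgb_ll)
  if (length(chans) != 3L) {
    stop("`rgb_ll` must supply exactly three channels", call. = FALSE)
  }
  check_matrix(nir_ll)
  if (!identical(dim(chans[[1]]), dim(nir_ll))) {
    stop("consistency error: colour and NIR coefficients differ in shape",
         call. = FALSE)
  }
  fusedch <- vector("list", 3L)
  for (i in 1:3) {
    e <- if (is.null(entropy_maps)) {
      entropy_filter(chans[[i]], window_side, bins)
    } else {
      entropy_maps[[i]]
    }
    w <- homogeneity(e)
    fusedch[[i]] <- chans[[i]] +
      local_weighted_convolution(w, nir_ll, window_side)
  }
  names(fusedch) <- c("R", "G", "B")
  structure(list(channels = fusedch, level = as.integer(level),
                 window_side = as.integer(window_side),
                 bins = as.integer(bins)),
            class = "fused_image")
}

# Global histogram entropy of one coefficient map, normalized by log2(bins).
subband_entropy <- function(x, bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  q <- quantize_levels(x, rng[1], rng[2], bins)
  p <- tabulate(as.vector(q) + 1L, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(bins)
}

#' Stopping rule on a sequence of per-level detail entropies
#'
#' Returns the smallest level `j >= 2` whose mean detail entropy differs from
#' the previous level's by less than `tol`; if the entropy never settles, the
#' deepest level is returned.
#'
#' @param entropies Numeric vector, `entropies[j]` the mean normalized detail
#'   entropy at level j.
#' @param tol Absolute difference tolerance.
#' @param max_levels Deepest admissible level (defaults to
#'   `length(entropies)`).
#' @return Integer level.
#' @export
fusion_level_from_entropies <- function(entropies, tol = 0.05,
                                        max_levels = length(entropies)) {
  max_levels <- as.integer(max_levels)
  if (max_levels < 2L) {
    stop("configuration error: `max_levels` must be at least 2",
         call. = FALSE)
  }
  for (j in 2:max_levels) {
    if (abs(entropies[j] - entropies[j - 1L]) < tol) return(j)
  }
  max_levels
}

#' Select the fusion level from colour detail entropies
#'
#' For each level j, the mean normalized histogram entropy over all nine
#' detail subbands (LH/HL/HH across R/G/B) is computed; fusion happens at the
#' first level at which this entropy stops changing by more than `tol`
#' between consecutive levels — the point at which deeper decomposition no
#' longer removes detail information.
#'
#' @param rgb_pyramids List of three `dwt_pyramid`s decomposed (with detail
#'   subbands retained) to at least `max_levels`.
#' @param max_levels Deepest admissible level (>= 2).
#' @param tol Entropy-difference tolerance (default 0.05).
#' @param bins Histogram resolution for the entropy estimate.
#' @return Integer fusion level in `2:max_levels`.
#' @export
select_fusion_level <- function(rgb_pyramids, max_levels = NULL, tol = 0.05,
                                bins = 256L) {
  stopifnot(is.list(rgb_pyramids), length(rgb_pyramids) == 3L)
  depth <- min(vapply(rgb_pyramids, function(p) length(p$levels), integer(1)))
  max_levels <- as.integer(max_levels %||% depth)
  if (max_levels < 2L) {
    stop("configuration error: `max_levels` must be at least 2",
         call. = FALSE)
  }
  if (max_levels > depth) {
    stop("pyramids are shallower than `max_levels`", call. = FALSE)
  }
  d <- vapply(seq_len(max_levels), function(j) {
    vals <- unlist(lapply(rgb_pyramids, function(p) {
      sb <- p$levels[[j]]
      c(subband_entropy(sb$lh, bins),
        subband_entropy(sb$hl, bins),
        subband_entropy(sb$hh, bins))
    }))
    mean(vals)
  }, numeric(1))
  fusion_level_from_entropies(d, tol, max_levels)
}

#' @export
print.fused_image <- function(x, ...) {
  cat(sprintf("<fused_image> %s at level %s (window %d, %d bins)\n",
              paste(dim(x$channels[[1]]), collapse = "x"),
              x$level, x$window_side, x$bins))
  invisible(x)
}
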