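#' Daubechies length-4 analysis/synthesis filter bank
#'
#' Returns the four low-pass taps
#' \eqn{h_0=(1+\sqrt3)/(4\sqrt2)}, \eqn{h_1=(3+\sqrt3)/(4\sqrt2)},
#' \eqn{h_2=(3-\sqrt3)/(4\sqrt2)}, \eqn{h_3=(1-\sqrt3)/(4\sqrt2)}
#' and the high-pass taps derived by the alternating flip
#' \eqn{g_k=(-1)^k h_{3-k}}, i.e. \eqn{(h_3, -h_2, h_1, -h_0)}.
#' The bank is orthonormal: `sum(low) == sqrt(2)`, `sum(low^2) == 1` and
#' `sum(low * high) == 0` (to machine precision), which is what gives the
#' transform its perfect-reconstruction and energy-preservation properties
#' under periodic extension.
#'
#' @return An object of class `filter_bank`: a list with numeric vectors
#'   `low` and `high`, each of length 4.
#' @examples
#' fb <- make_db4_filters()
#' sum(fb$low)    # sqrt(2)
#' sum(fb$low^2)  # 1
#' @export
make_db4_filters <- function() {
  s3 <- sqrt(3)
  low <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  high <- c(1, -1, 1, -1) * rev(low)
  structure(list(low = low, high = high), class = "filter_bank")
}

# One analysis step along dim 1 (rows): correlate with `taps` under periodic
# extension, keep even-indexed (0-based) output samples. nrow(x) must be even.
analyze_axis <- function(x, taps) {
  n <- nrow(x)
  m <- 2L * (seq_len(n %/% 2L) - 1L)
  out <- 0
  for (k in 0:3) {
    idx <- ((m + k) %% n) + 1L
    out <- out + taps[k + 1L] * x[idx, , drop = FALSE]
  }
  out
}

# Inverse of analyze_axis: upsample-and-filter both subbands onto n rows.
synthesize_axis <- function(approx, detail, bank, n) {
  out <- matrix(0, n, ncol(approx))
  m <- 2L * (seq_len(nrow(approx)) - 1L)
  for (k in 0:3) {
    idx <- ((m + k) %% n) + 1L
    out[idx, ] <- out[idx, ] +
      bank$low[k + 1L] * approx + bank$high[k + 1L] * detail
  }
  out
}

#' Single-level 2-D wavelet analysis
#'
#' Separable row/column filtering with the low- and high-pass taps followed
#' by dyadic downsampling (even-phase, 0-based), producing the four subbands
#' LL, LH, HL, HH. Boundaries are handled by periodic (circular) extension;
#' an odd trailing row/column is first padded by edge replication and the pad
#' is recorded so [synthesize_level()] can crop it away. Each subband has
#' `ceiling(n/2)` samples per axis.
#'
#' Subband naming: `lh` is low-pass along rows / high-pass along columns,
#' `hl` the converse.
#'
#' @param image Numeric matrix, both dimensions at least 4, all values finite.
#' @param bank A [make_db4_filters()] filter bank.
#' @return An object of class `subband_set`: list with matrices `ll`, `lh`,
#'   `hl`, `hh`, the `input_shape` of `image`, and the recorded `pad`.
#' @export
analyze_level <- function(image, bank = make_db4_filters()) {
  check_matrix(image)
  if (min(dim(image)) < 4) {
    stop("input-size error: both image dimensions must be at least 4",
         call. = FALSE)
  }
  input_shape <- dim(image)
  pad <- input_shape %% 2L
  if (pad[1] == 1L) image <- rbind(image, image[nrow(image), ])
  if (pad[2] == 1L) image <- cbind(image, image[, ncol(image)])

  lo_r <- analyze_axis(image, bank$low)
  hi_r <- analyze_axis(image, bank$high)
  structure(list(
    ll = t(analyze_axis(t(lo_r), bank$low)),
    lh = t(analyze_axis(t(lo_r), bank$high)),
    hl = t(analyze_axis(t(hi_r), bank$low)),
    hh = t(analyze_axis(t(hi_r), bank$high)),
    level = 1L,
    input_shape = input_shape,
    pad = pad
  ), class = "subband_set")
}

#' Single-level 2-D wavelet synthesis
#'
#' Inverse of [analyze_level()]: upsample-and-filter synthesis along columns
#' then rows, followed by cropping of any replication pad, so that
#' `synthesize_level(analyze_level(x), target_shape = dim(x))` recovers `x`
#' to machine precision.
#'
#' @param bands A `subband_set` (the `ll` may have been modified).
#' @param bank A [make_db4_filters()] filter bank.
#' @param target_shape Integer vector `(rows, cols)` of the image to recover;
#'   defaults to the recorded `input_shape`.
#' @return Numeric matrix of dimension `target_shape`.
#' @export
synthesize_level <- function(bands, bank = make_db4_filters(),
                             target_shape = bands$input_shape) {
  target_shape <- as.integer(target_shape)
  half <- as.integer(ceiling(target_shape / 2))
  for (nm in c("ll", "lh", "hl", "hh")) {
    if (!identical(dim(bands[[nm]]), half)) {
      stop(sprintf(
        "consistency error: subband `%s` has shape %s, expected %s for target %s",
        nm, paste(dim(bands[[nm]]), collapse = "x"),
        paste(half, collapse = "x"), paste(target_shape, collapse = "x")
      ), call. = FALSE)
    }
  }
  n_pad <- half * 2L
  lo_r <- t(synthesize_axis(t(bands$ll), t(bands$lh), bank, n_pad[2]))
  hi_r <- t(synthesize_axis(t(bands$hl), t(bands$hh), bank, n_pad[2]))
  x <- synthesize_axis(lo_r, hi_r, bank, n_pad[1])
  x[seq_len(target_shape[1]), seq_len(target_shape[2]), drop = FALSE]
}

#' Multi-level wavelet decomposition of one channel
#'
#' Iteratively applies [analyze_level()] to the running approximation (LL)
#' coefficient. When `zero_highpass` is set, the three detail subbands are
#' replaced by zeros at every level before storage — the noise-suppression
#' step that removes unstructured fine-scale background speckle — while the
#' running LL itself is unaffected.
#'
#' @param image Numeric matrix.
#' @param levels Number of decomposition levels (>= 1); the analysis input at
#'   every level must retain at least 4 samples per axis.
#' @param zero_highpass Logical; store zeroed detail subbands.
#' @param bank Filter bank.
#' @param channel_id Optional label ("R", "G", "B", "NIR").
#' @return An object of class `dwt_pyramid`: list with `channel_id`, `levels`
#'   (list of `subband_set`, level 1 first), `original_shape`, and
#'   `zero_highpass`.
#' @export
decompose <- function(image, levels, zero_highpass = FALSE,
                      bank = make_db4_filters(), channel_id = NA_character_) {
  check_matrix(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be at least 1", call. = FALSE)
  out <- vector("list", levels)
  cur <- image
  for (j in seq_len(levels)) {
    if (min(dim(cur)) < 4) {
      stop(sprintf(
        "input-size error: level %d analysis needs >= 4 samples per axis (got %s); reduce `levels`",
        j, paste(dim(cur), collapse = "x")
      ), call. = FALSE)
    }
    sb <- analyze_level(cur, bank)
    sb$level <- j
    cur <- sb$ll
    if (zero_highpass) {
      sb$lh[] <- 0
      sb$hl[] <- 0
      sb$hh[] <- 0
    }
    out[[j]] <- sb
  }
  structure(list(
    channel_id = channel_id,
    levels = out,
    original_shape = dim(image),
    zero_highpass = zero_highpass
  ), class = "dwt_pyramid")
}

#' Full reconstruction of a decomposition pyramid
#'
#' Applies [synthesize_level()] from the deepest level outward, starting from
#' the deepest stored LL and using each level's stored detail subbands,
#' cropping back to the original shape.
#'
#' @param pyramid A `dwt_pyramid`.
#' @param bank Filter bank.
#' @return Numeric matrix of the pyramid's `original_shape`.
#' @export
reconstruct <- function(pyramid, bank = make_db4_filters()) {
  if (!inherits(pyramid, "dwt_pyramid")) {
    stop("`pyramid` must be a dwt_pyramid", call. = FALSE)
  }
  levs <- pyramid$levels
  x <- levs[[length(levs)]]$ll
  for (j in rev(seq_along(levs))) {
    sb <- levs[[j]]
    if (!identical(dim(x), dim(sb$ll))) {
      stop("consistency error: pyramid levels are not consecutive",
           call. = FALSE)
    }
    sb$ll <- x
    x <- synthesize_level(sb, bank, target_shape = sb$input_shape)
  }
  x
}

# Shallow pyramid truncated at level J (metadata for mask reconstruction).
truncate_pyramid <- function(pyramid, J) {
  stopifnot(J >= 1, J <= length(pyramid$levels))
  pyramid$levels <- pyramid$levels[seq_len(J)]
  pyramid
}

#' @export
print.dwt_pyramid <- function(x, ...) {
  cat(sprintf(
    "<dwt_pyramid> channel=%s levels=%d original=%s zero_highpass=%s\n",
    x$channel_id, length(x$levels),
    paste(x$original_shape, collapse = "x"), x$zero_highpass
  ))
  invisible(x)
}
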