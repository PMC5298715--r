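# Independent brute-force oracles, deliberately written as plain nested loops
# so they share no code path with the package implementations.

# Per-pixel windowed histogram entropy with zero padding (bits / log2(w^2)).
brute_entropy_filter <- function(x, window_side = 3L, bins = 256L) {
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(0, nr, nc)
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(out)
  h <- (window_side - 1L) %/% 2L
  w2 <- window_side^2
  qof <- function(v) min(max(floor((v - lo) / (hi - lo) * bins), 0), bins - 1)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      counts <- integer(bins)
      for (di in -h:h) {
        for (dj in -h:h) {
          ii <- i + di
          jj <- j + dj
          v <- if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) x[ii, jj] else 0
          q <- qof(v)
          counts[q + 1L] <- counts[q + 1L] + 1L
        }
      }
      p <- counts[counts > 0] / w2
      out[i, j] <- -sum(p * log2(p)) / log2(w2)
    }
  }
  out
}

# Windowed mean of the elementwise product, zero padding outside.
brute_window_mean <- function(w, f, window_side = 3L) {
  nr <- nrow(w)
  nc <- ncol(w)
  h <- (window_side - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (dj in -h:h) {
        for (di in -h:h) {
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            acc <- acc + w[ii, jj] * f[ii, jj]
          }
        }
      }
      out[i, j] <- acc / window_side^2
    }
  }
  out
}

# Exhaustive Otsu: scan every candidate cut on the same 256-bin quantization.
brute_otsu_cut <- function(x, bins = 256L) {
  lo <- min(x)
  hi <- max(x)
  q <- pmin(pmax(floor((x - lo) / (hi - lo) * bins), 0), bins - 1)
  n <- length(q)
  best <- -Inf
  best_t <- 0L
  for (t in 0:(bins - 2L)) {
    g0 <- q <= t
    n0 <- sum(g0)
    if (n0 == 0 || n0 == n) next
    mu0 <- mean(q[g0])
    mu1 <- mean(q[!g0])
    sb <- (n0 / n) * (1 - n0 / n) * (mu0 - mu1)^2
    if (sb > best + 1e-12) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# Quick scene used by several tests: small, fast, deterministic.
small_scene_config <- function(seed, ...) {
  scene_config(size = c(128L, 128L), n_fruits = 3L,
               fruit_radius_range = c(10, 16), seed = seed, ...)
}

mask_overlap <- function(a, b) {
  sum(a > 0.5 & b > 0.5) / sum((a > 0.5) | (b > 0.5))
}
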