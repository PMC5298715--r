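#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# Accept a H x W x 3 array or a list of three matrices; return list(R, G, B).
as_channel_list <- function(x) {
  if (is.list(x)) {
    stopifnot(length(x) >= 3)
    chans <- x[seq_len(length(x))]
  } else if (is.array(x) && length(dim(x)) == 3) {
    chans <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  } else if (is.matrix(x)) {
    chans <- list(x)
  } else {
    stop("expected a H x W x C array or a list of matrices", call. = FALSE)
  }
  d <- dim(chans[[1]])
  for (ch in chans) {
    if (!identical(dim(ch), d)) stop("channels differ in shape", call. = FALSE)
  }
  chans
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Quantize values into `bins` integer levels 0..bins-1 over [lo, hi].
quantize_levels <- function(x, lo, hi, bins) {
  if (hi <= lo) return(array(0L, dim = dim(x) %||% length(x)))
  q <- floor((x - lo) / (hi - lo) * bins)
  q <- pmin(pmax(q, 0), bins - 1)
  storage.mode(q) <- "integer"
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
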