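#' Pair-counting weighted F-measure between two masks
#'
#' With \eqn{a = |R \cap C|}, \eqn{b = |C \setminus R|},
#' \eqn{c = |R \setminus C|} (pixel counts for reference R and candidate C),
#' the default `"pair"` counting takes binomial coefficients
#' \eqn{TP = \binom{a}{2}}, \eqn{FP = \binom{b}{2}}, \eqn{FN = \binom{c}{2}}
#' (with \eqn{\binom{0}{2} = \binom{1}{2} = 0}); the `"pixel"` variant uses
#' the raw counts \eqn{TP = a, FP = b, FN = c}. Then
#' \deqn{P = TP/(TP+FP), \quad R = TP/(TP+FN), \quad
#'       F = 1 / (\alpha/P + (1-\alpha)/R),}
#' with `F = 0` whenever P or R is 0, and the convention P = R = F = 1 when
#' both masks are empty (perfect trivial agreement). `alpha` near 1 weights
#' precision: false positives (background classified as fruit) dominate the
#' score, the regime the comparison study operates in (alpha = 0.98).
#'
#' @param reference,candidate Binary (0/1 or logical) matrices of equal shape.
#' @param alpha Precision weight in (0, 1).
#' @param counting `"pair"` (binomial-coefficient counts, the default) or
#'   `"pixel"`.
#' @return A one-row [tibble::tibble()] with columns `precision`, `recall`,
#'   `f_measure`, `alpha`, `tp`, `fp`, `fn`, `counting`.
#' @export
pair_f_measure <- function(reference, candidate, alpha = 0.98,
                           counting = c("pair", "pixel")) {
  counting <- match.arg(counting)
  if (!identical(dim(reference), dim(candidate))) {
    stop("consistency error: masks differ in shape", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("`alpha` must lie strictly in (0, 1)", call. = FALSE)
  }
  ref <- reference > 0.5
  cand <- candidate > 0.5
  a <- sum(ref & cand)
  b <- sum(cand & !ref)
  cc <- sum(ref & !cand)

  if (a + cc == 0L && a + b == 0L) {
    message("both masks empty; reporting perfect trivial agreement")
    return(tibble::tibble(precision = 1, recall = 1, f_measure = 1,
                          alpha = alpha, tp = 0, fp = 0, fn = 0,
                          counting = counting))
  }

  choose2 <- function(m) m * (m - 1) / 2
  if (counting == "pair") {
    tp <- choose2(a); fp <- choose2(b); fn <- choose2(cc)
  } else {
    tp <- a; fp <- b; fn <- cc
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec > 0 && rec > 0) 1 / (alpha / prec + (1 - alpha) / rec) else 0
  tibble::tibble(precision = prec, recall = rec, f_measure = f,
                 alpha = alpha, tp = tp, fp = fp, fn = fn,
                 counting = counting)
}

#' Fraction of ground-truth fruits identified by a mask
#'
#' A reference fruit (connected component) counts as identified when the
#' candidate mask covers at least `overlap_min` of its pixels.
#'
#' @param reference_components Either an integer labelled matrix (0 =
#'   background, 1..n = disjoint fruit regions) or a list of pixel-index
#'   vectors, one per fruit.
#' @param candidate Binary mask, same underlying shape.
#' @param overlap_min Minimum covered fraction (default 0.5).
#' @return Identified fraction in \[0, 1\].
#' @export
identification_rate <- function(reference_components, candidate,
                                overlap_min = 0.5) {
  cand <- candidate > 0.5
  if (is.matrix(reference_components)) {
    labs <- sort(unique(as.vector(reference_components)))
    labs <- labs[labs > 0]
    comps <- lapply(labs, function(l) which(reference_components == l))
  } else {
    comps <- reference_components
  }
  if (length(comps) == 0L) {
    stop("data error: no reference fruit components", call. = FALSE)
  }
  hit <- vapply(comps, function(idx) {
    sum(cand[idx]) / length(idx) >= overlap_min
  }, logical(1))
  mean(hit)
}
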