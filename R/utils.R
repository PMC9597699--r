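#' Average precision of a ranking
#'
#' Step-wise average precision (the mean of the precision at each positive's
#' rank), the standard estimator of the area under the precision-recall
#' curve for a ranked list. Ties in `scores` are broken by input order, so
#' callers wanting a specific tie policy must pre-order their input.
#'
#' @param scores Numeric vector; larger means ranked earlier.
#' @param labels Logical (or 0/1) vector, `TRUE` for positives.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels)) stop("average precision needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  mean(prec_at[y])
}

#' Combine two one-sided p-values with Stouffer's method
#'
#' Converts each p to a standard-normal quantile z = qnorm(1 - p), combines
#' as (z1 + z2) / sqrt(2) and returns the upper-tail probability. Extreme
#' p-values are clamped away from 0 and 1 so the z-scores stay finite.
#'
#' @param p1,p2 One-sided p-values in (0, 1).
#' @return Combined one-sided p-value.
#' @export
stouffer_p <- function(p1, p2) {
  eps <- 1e-15
  z1 <- stats::qnorm(1 - min(max(p1, eps), 1 - eps))
  z2 <- stats::qnorm(1 - min(max(p2, eps), 1 - eps))
  stats::pnorm((z1 + z2) / sqrt(2), lower.tail = FALSE)
}

# one-sided (over-representation) hypergeometric tail:
# P(X >= overlap) with `k_ann` annotated among `n_bg`, drawing `n_draw`.
hyper_p <- function(overlap, k_ann, n_bg, n_draw) {
  stats::phyper(overlap - 1, k_ann, n_bg - k_ann, n_draw, lower.tail = FALSE)
}
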