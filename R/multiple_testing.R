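#' Histogram-based estimate of the number of true nulls
#'
#' Partitions [0, 1] into `B` equal right-closed bins (p = 0 counts in bin
#' 1) and iterates: given a current estimate m0, take the leftmost bin whose
#' count does not exceed m0 / B (the last bin if none), and re-estimate m0
#' as the total count from that bin rightward rescaled to all B bins.
#' Starting from m0 = m, the iteration runs to a fixed point (at most 100
#' steps) and the result is clamped to [0, m].
#'
#' @param p P-values in [0, 1]; `NA`s are dropped.
#' @param B Number of histogram bins (default 20).
#' @return Estimated number of true null hypotheses.
#' @export
estimate_m0 <- function(p, B = 20L) {
  p <- p[!is.na(p)]
  m <- length(p)
  if (m == 0L) stop("no p-values")
  if (B < 2L) stop("B must be >= 2")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  bin <- pmax(ceiling(p * B), 1L)
  counts <- tabulate(bin, nbins = B)
  m0 <- m
  for (iter in 1:100) {
    small <- which(counts <= m0 / B)
    bstar <- if (length(small)) small[1L] else B
    m0_new <- sum(counts[bstar:B]) * B / (B - bstar + 1L)
    m0_new <- min(max(m0_new, 0), m)
    if (identical(m0_new, m0)) break
    m0 <- m0_new
  }
  m0
}

#' Storey q-values
#'
#' Converts p-values to q-values with a plug-in estimate of the number of
#' true nulls: with p sorted ascending, `q_(i) = min_{j >= i} min(1,
#' m0 * p_(j) / j)`, mapped back to input order. Tied p-values share a
#' q-value. Rejecting all genes with q <= alpha approximately controls the
#' false discovery rate at alpha.
#'
#' @param p P-values (NAs propagate).
#' @param m0 Estimated number of true nulls; default [estimate_m0()] on the
#'   non-missing p-values.
#' @return Numeric vector of q-values with attribute `m0`.
#' @export
qvalues <- function(p, m0 = estimate_m0(p)) {
  ok <- !is.na(p)
  pp <- p[ok]
  m <- length(pp)
  if (m == 0L) stop("no p-values")
  if (m0 < 0 || m0 > m) stop("m0 must be in [0, m]")
  ord <- order(pp)
  ps <- pp[ord]
  q_sorted <- rev(cummin(rev(pmin(1, m0 * ps / seq_len(m)))))
  # ties share the tail minimum (the value at the first tied position)
  first_of_tie <- !duplicated(ps)
  q_sorted <- q_sorted[cummax(seq_len(m) * first_of_tie)]
  q <- rep(NA_real_, length(p))
  qq <- numeric(m)
  qq[ord] <- q_sorted
  q[ok] <- qq
  attr(q, "m0") <- m0
  q
}

#' Count discoveries at an FDR threshold
#'
#' @param q Q-values.
#' @param alpha FDR threshold in (0, 1); genes with `q <= alpha` are counted
#'   (boundary included).
#' @return Integer number of rejections.
#' @export
count_rejections <- function(q, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  sum(q <= alpha, na.rm = TRUE)
}
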