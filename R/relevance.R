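#' p.05 relevance of a variable
#'
#' The simplest relevance measure for a variable's vector of per-gene
#' p-values: the number of p-values strictly less than 0.05. Missing values
#' (genes whose fits failed) are excluded.
#'
#' @param p P-values for one variable, one per gene.
#' @param threshold Count p-values strictly below this value (default 0.05).
#' @return Integer count.
#' @export
relevance_p05 <- function(p, threshold = 0.05) {
  ok <- !is.na(p)
  if (!any(ok)) stop("all p-values are missing")
  sum(p[ok] < threshold)
}

#' Least concave majorant of a p-value ECDF
#'
#' Computes the least concave majorant (Grenander geometry) of the
#' empirical distribution function of `p`, anchored at (0, 0) and (1, 1).
#' It is the upper convex hull of the ECDF's jump points, found by a
#' monotone-chain scan; the returned knots are the hull vertices.
#'
#' @param p P-values in [0, 1]; NAs dropped.
#' @return A list of class `lcm_function` with increasing `x`, values `y`,
#'   and `m` (the number of p-values used). Piecewise-linear between knots.
#' @export
lcm_ecdf <- function(p) {
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  m <- length(p)
  if (m == 0L) stop("no p-values")
  sp <- sort(p)
  ux <- unique(sp)
  uy <- cumsum(tabulate(match(sp, ux), nbins = length(ux))) / m
  x <- c(0, ux, 1)
  y <- c(0, uy, 1)
  # at duplicated x (p = 0 or p = 1 present) keep the larger ECDF value
  keep <- rev(!duplicated(rev(x)))
  x <- x[keep]; y <- y[keep]

  # upper hull, x increasing: pop while the turn is not strictly concave
  hx <- numeric(length(x)); hy <- numeric(length(x))
  h <- 0L
  for (i in seq_along(x)) {
    while (h >= 2L) {
      cross <- (hx[h] - hx[h - 1L]) * (y[i] - hy[h - 1L]) -
               (hy[h] - hy[h - 1L]) * (x[i] - hx[h - 1L])
      if (cross >= -1e-15) h <- h - 1L else break
    }
    h <- h + 1L
    hx[h] <- x[i]; hy[h] <- y[i]
  }
  structure(list(x = hx[seq_len(h)], y = hy[seq_len(h)], m = m),
            class = "lcm_function")
}

#' Evaluate a least concave majorant
#'
#' @param lcm An [lcm_ecdf()] result.
#' @param x Points in [0, 1].
#' @return Interpolated LCM values.
#' @export
lcm_eval <- function(lcm, x) {
  stats::approx(lcm$x, lcm$y, xout = x, rule = 2)$y
}

#' GKS relevance of a variable
#'
#' The Grenander-Kolmogorov-Smirnov relevance measure: `sqrt(m)` times the
#' supremum over (0, 1) of the least concave majorant of the p-value ECDF
#' minus the identity. Because the LCM is piecewise linear, the supremum is
#' attained at a hull knot, so knot evaluation is exact; the anchors
#' contribute 0, making the statistic non-negative. Large values indicate
#' an excess of small p-values over uniformity, i.e. relevance of the
#' variable for some genes.
#'
#' @param p P-values for one variable; NAs dropped (m reduced accordingly).
#' @return The GKS statistic, a non-negative scalar in [0, sqrt(m)].
#' @export
relevance_gks <- function(p) {
  lcm <- lcm_ecdf(p)
  max(0, sqrt(lcm$m) * max(lcm$y - lcm$x))
}

#' Relevance of a variable's p-value vector
#'
#' Dispatches to [relevance_p05()] or [relevance_gks()].
#'
#' @param p P-values for one variable.
#' @param measure `"p05"` or `"gks"`.
#' @return Relevance score (numeric scalar).
#' @export
relevance <- function(p, measure = c("p05", "gks")) {
  measure <- match.arg(measure)
  switch(measure, p05 = relevance_p05(p), gks = relevance_gks(p))
}
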