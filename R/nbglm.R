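#' @useDynLib covsel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fit negative binomial log-linear models to a count matrix
#'
#' Batched iteratively reweighted least squares over genes with a log link,
#' known per-sample offsets, and a fixed per-gene dispersion `omega`
#' (Var = mu + omega * mu^2; `omega = 0` is the Poisson limit). Deviance is
#' twice the gap between the saturated and fitted log-likelihoods, with the
#' `y log y` term taken as 0 for zero counts. Step-halving guards each
#' update; convergence is declared when the relative deviance change drops
#' below `tol`.
#'
#' @param counts Count matrix (genes x samples) or a single count vector.
#' @param X Design matrix (n x p) or a [design_matrix()] object.
#' @param offsets Per-sample offsets on the log scale.
#' @param omega Per-gene NB dispersion(s), recycled to the number of genes.
#' @param maxit Maximum IRLS iterations (default 50).
#' @param tol Relative deviance convergence tolerance (default 1e-8).
#' @param beta_init Optional matrix of warm-start coefficients (genes x p).
#' @return A list with `beta` (genes x p), `mu` (fitted means), `deviance`,
#'   `iterations`, and `converged` per gene.
#' @export
nb_glm <- function(counts, X, offsets, omega, maxit = 50L, tol = 1e-8,
                   beta_init = NULL) {
  if (inherits(X, "design_matrix")) X <- X$matrix
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  m <- nrow(counts)
  stopifnot(ncol(counts) == nrow(X), length(offsets) == nrow(X))
  if (nrow(X) < ncol(X)) stop("more coefficients than samples")
  omega <- rep_len(omega, m)
  if (any(omega < 0)) stop("omega must be >= 0")
  if (!is.null(beta_init)) {
    beta_init <- matrix(as.numeric(beta_init), nrow = m)
    stopifnot(ncol(beta_init) == ncol(X))
  }
  fit <- .nb_glm_batch(counts, X, as.numeric(offsets), omega,
                       as.integer(maxit), tol, beta_init)
  colnames(fit$beta) <- colnames(X)
  if (any(!is.finite(fit$mu))) stop("non-finite fitted means")
  fit
}

#' Fit one gene's negative binomial GLM
#'
#' Single-gene wrapper around [nb_glm()] returning a `gene_fit` record.
#'
#' @inheritParams nb_glm
#' @param y Count vector for one gene.
#' @return A list of class `gene_fit` with `beta`, `mu`, `deviance`,
#'   `omega`, `converged`, and `iterations`.
#' @export
fit_nb_glm <- function(y, X, offsets, omega, maxit = 50L, tol = 1e-8) {
  fit <- nb_glm(matrix(y, nrow = 1L), X, offsets, omega,
                maxit = maxit, tol = tol)
  structure(list(beta = drop(fit$beta), mu = drop(fit$mu),
                 deviance = fit$deviance[1L], omega = omega,
                 converged = fit$converged[1L],
                 iterations = fit$iterations[1L]),
            class = "gene_fit")
}

#' Moment estimate of the NB dispersion
#'
#' Estimates omega in Var = mu + omega * mu^2 by the method of moments,
#' `max(0, sum((y - mu)^2 - mu) / sum(mu^2))`, with fitted means from a
#' Poisson fit of the same design. Floored at 0, so data no more variable
#' than Poisson give omega = 0.
#'
#' @inheritParams fit_nb_glm
#' @return Non-negative dispersion estimate. If the Poisson mean fit fails
#'   to converge the moment value is still returned, with a warning.
#' @export
estimate_nb_dispersion <- function(y, X, offsets) {
  om <- estimate_nb_dispersion_matrix(matrix(y, nrow = 1L), X, offsets)
  om[1L]
}

# vectorized over genes; shared Poisson fit
estimate_nb_dispersion_matrix <- function(counts, X, offsets) {
  if (inherits(X, "design_matrix")) X <- X$matrix
  if (nrow(X) < ncol(X) + 1L)
    stop("need n >= p + 1 samples to estimate dispersion")
  fit <- nb_glm(counts, X, offsets, omega = 0)
  if (any(!fit$converged))
    warning(sum(!fit$converged), " gene(s): Poisson mean fit did not converge; ",
            "moment dispersion returned from last iterate")
  mu <- fit$mu
  num <- rowSums((counts - mu)^2 - mu)
  pmax(0, num / rowSums(mu^2))
}

# trended alternative: pool gene-wise moment estimates within bins of mean
# count and assign each gene its bin average
estimate_nb_dispersion_trended <- function(counts, X, offsets, nbins = 10L) {
  om <- estimate_nb_dispersion_matrix(counts, X, offsets)
  mc <- rowMeans(counts)
  if (length(om) < 2L * nbins) return(rep(mean(om), length(om)))
  bins <- cut(rank(mc, ties.method = "first"), breaks = nbins, labels = FALSE)
  stats::ave(om, bins, FUN = mean)
}

#' Likelihood ratio statistic for nested NB fits
#'
#' For a full fit and a reduced fit (same dispersion, same offsets, reduced
#' design = full design minus one variable's column block), the LR statistic
#' is the deviance difference, clipped at zero. A negative difference beyond
#' tolerance signals a poorly converged reduced fit and triggers a warning;
#' callers should refit the reduced model warm-started from the full fit.
#'
#' @param full,reduced `gene_fit` objects (or lists with a `deviance`).
#' @param df1 Width of the dropped column block (numerator df).
#' @return List of class `lrt_result` with `stat` and `df1`.
#' @export
lrt_stat <- function(full, reduced, df1) {
  stat <- reduced$deviance - full$deviance
  if (any(stat < -1e-6))
    warning("reduced-model deviance below full-model deviance (",
            format(min(stat)), "); statistic clipped at 0")
  structure(list(stat = pmax(stat, 0), df1 = as.integer(df1)),
            class = "lrt_result")
}
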