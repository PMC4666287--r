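#' Gene-wise quasi-dispersion
#'
#' The raw quasi-dispersion is the full-model deviance divided by its
#' residual degrees of freedom. It measures lack of fit relative to the
#' working NB model and is the denominator of the quasi-likelihood F
#' statistic (after shrinkage across genes).
#'
#' @param deviance Full-model deviance(s).
#' @param df_res Residual degrees of freedom, n - p, of the full model.
#' @return Raw quasi-dispersion(s), `deviance / df_res`.
#' @export
quasi_dispersion <- function(deviance, df_res) {
  if (df_res < 1L) stop("model saturates the sample (df_res = 0)")
  deviance / df_res
}

# Newton solve of trigamma(y) = x; x > 0
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (!is.finite(y) || y <= 0) return(Inf)
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Shrink quasi-dispersions across genes
#'
#' Stabilizes gene-wise quasi-dispersions by borrowing information across
#' genes. A natural cubic spline (4 df) of log quasi-dispersion on mean log
#' count gives a trend; the spread of `log(phi_hat / trend)` in excess of
#' the chi-square sampling noise `trigamma(df_res / 2)` is matched, on the
#' log scale, to a scaled inverse-chi-square prior to estimate the prior
#' degrees of freedom `d0`. The shrunken value is the convex combination
#' `(d0 * trend + df_res * phi_hat) / (d0 + df_res)`; when the observed
#' spread does not exceed the sampling noise, `d0 = Inf` and all genes are
#' shrunk fully to the trend.
#'
#' @param phi_hat Raw quasi-dispersions (one per gene).
#' @param mean_log_counts Per-gene mean log counts (trend covariate).
#' @param df_res Residual degrees of freedom of the full model.
#' @param d0 Optional fixed prior df, bypassing estimation.
#' @param spline_df Spline degrees of freedom for the trend (default 4);
#'   with fewer than 10 genes the trend falls back to a constant.
#' @return List of class `quasi_dispersion_set`: `phi_hat`, `phi_tilde`,
#'   `d0`, `trend`, `df_res`.
#' @export
shrink_dispersions <- function(phi_hat, mean_log_counts, df_res,
                               d0 = NULL, spline_df = 4L) {
  m <- length(phi_hat)
  stopifnot(length(mean_log_counts) == m, df_res >= 1L)
  usable <- is.finite(phi_hat) & phi_hat > 1e-10
  if (any(!is.finite(phi_hat)))
    warning(sum(!is.finite(phi_hat)),
            " non-finite quasi-dispersion(s) shrunk to the trend")

  if (sum(usable) < 10L || length(unique(mean_log_counts[usable])) < 5L) {
    trend <- rep(if (any(usable)) exp(mean(log(phi_hat[usable]))) else 1,
                 m)
  } else {
    lfit <- stats::lm(log(phi_hat[usable]) ~
                        splines::ns(mean_log_counts[usable], df = spline_df))
    basis <- splines::ns(mean_log_counts[usable], df = spline_df)
    trend <- exp(drop(cbind(1, stats::predict(basis, mean_log_counts)) %*%
                        stats::coef(lfit)))
  }
  trend <- pmax(trend, 1e-10)

  if (is.null(d0)) {
    z <- log(phi_hat[usable] / trend[usable])
    if (length(z) < 3L) {
      d0 <- Inf
    } else {
      excess <- stats::var(z) - trigamma(df_res / 2)
      d0 <- if (!is.finite(excess) || excess <= 1e-10) Inf
            else 2 * trigamma_inverse(excess)
    }
  }
  if (d0 < 0) stop("d0 must be positive")

  phi_tilde <- if (is.infinite(d0)) trend
               else (d0 * trend + df_res * phi_hat) / (d0 + df_res)
  phi_tilde[!usable] <- trend[!usable]
  phi_tilde <- pmax(phi_tilde, 1e-10)
  structure(list(phi_hat = phi_hat, phi_tilde = phi_tilde, d0 = d0,
                 trend = trend, df_res = df_res),
            class = "quasi_dispersion_set")
}

#' Quasi-likelihood F-test p-value
#'
#' Scales the likelihood-ratio statistic by the shrunken quasi-dispersion
#' and refers `F = (stat / df1) / phi_tilde` to a central F distribution
#' with `df1` and `d0 + df_res` degrees of freedom. The denominator df is
#' never below the residual df of the full model; infinite `d0` gives the
#' scaled chi-square limit.
#'
#' @param stat LR statistic(s), non-negative.
#' @param df1 Numerator df (width of the tested coefficient block).
#' @param phi_tilde Shrunken quasi-dispersion(s); floored at 1e-8.
#' @param df_res Residual df of the full model.
#' @param d0 Prior df from [shrink_dispersions()] (may be `Inf`).
#' @return Upper-tail p-value(s) in [0, 1].
#' @export
ql_f_test <- function(stat, df1, phi_tilde, df_res, d0) {
  if (any(stat < 0, na.rm = TRUE)) stop("negative LR statistic; clip first")
  phi <- pmax(phi_tilde, 1e-8)
  Fstat <- (stat / df1) / phi
  if (is.infinite(d0)) {
    stats::pchisq(df1 * Fstat, df = df1, lower.tail = FALSE)
  } else {
    stats::pf(Fstat, df1 = df1, df2 = d0 + df_res, lower.tail = FALSE)
  }
}

# One model-fitting pass for the variable set S: moment NB dispersions
# (trended by default) from a Poisson fit of the full model, NB fits of the
# full model, deviance-based quasi-dispersions and their shrinkage. Shared
# by test_variable, test_all_variables and de_test.
ql_full_fit <- function(counts, ct, offsets, S,
                        dispersion = c("trended", "gene")) {
  dispersion <- match.arg(dispersion)
  dm <- design_matrix(ct, S)
  n <- nrow(dm$matrix); p <- ncol(dm$matrix)
  df_res <- n - p
  if (df_res < 1L) stop("model for S saturates the sample")
  omega <- switch(dispersion,
    gene = estimate_nb_dispersion_matrix(counts, dm, offsets),
    trended = estimate_nb_dispersion_trended(counts, dm, offsets))
  full <- nb_glm(counts, dm, offsets, omega)
  phi_hat <- quasi_dispersion(full$deviance, df_res)
  shr <- shrink_dispersions(phi_hat, log(rowMeans(counts) + 0.5), df_res)
  list(dm = dm, omega = omega, full = full, df_res = df_res, shrink = shr)
}

# p-values for dropping variable j, given a ql_full_fit
ql_test_reduced <- function(counts, offsets, fit, j) {
  red <- drop_block(fit$dm, j)
  keep <- setdiff(seq_len(ncol(fit$dm$matrix)),
                  fit$dm$blocks[[as.character(j)]])
  rfit <- nb_glm(counts, red$matrix, offsets, fit$omega)
  stat <- rfit$deviance - fit$full$deviance
  if (any(stat < -1e-6, na.rm = TRUE)) {
    # warm start the offenders from the full fit's coefficients
    bad <- which(stat < -1e-6)
    refit <- nb_glm(counts[bad, , drop = FALSE], red$matrix, offsets,
                    fit$omega[bad],
                    beta_init = fit$full$beta[bad, keep, drop = FALSE])
    stat[bad] <- refit$deviance - fit$full$deviance[bad]
  }
  stat <- pmax(stat, 0)
  p <- ql_f_test(stat, red$df1, fit$shrink$phi_tilde, fit$df_res,
                 fit$shrink$d0)
  failed <- !is.finite(fit$full$deviance) | !is.finite(rfit$deviance)
  p[failed] <- NaN
  p
}

#' Quasi-likelihood test of one variable in a model
#'
#' For every gene, fits the NB log-linear model with the variables in `S`
#' and the reduced model without variable `j` (same gene-wise dispersion
#' and offsets), and converts the deviance difference to a p-value with the
#' quasi-likelihood F-test. Dispersion shrinkage is computed once from the
#' full model on `S`. Genes whose fits fail get `NaN`.
#'
#' @param counts Count matrix (genes x samples).
#' @param ct A [covariate_table()].
#' @param offsets Per-sample log-scale offsets.
#' @param S Variable index set (must contain 1).
#' @param j Variable to test, an element of `S`.
#' @param dispersion `"trended"` (binned common trend of the moment
#'   estimates, default) or `"gene"` (per-gene moment estimate). The
#'   trended mode leaves genuine gene-to-gene dispersion differences to be
#'   absorbed by the quasi-dispersion, which is what calibrates the
#'   F-test's denominator degrees of freedom.
#' @return Numeric vector of p-values, one per gene, with attributes
#'   `variable` and `S`.
#' @export
test_variable <- function(counts, ct, offsets, S, j,
                          dispersion = c("trended", "gene")) {
  counts <- validate_counts(counts)
  S <- sort(unique(as.integer(S)))
  if (!j %in% S) stop("j must be in S")
  fit <- ql_full_fit(counts, ct, offsets, S, dispersion)
  p <- ql_test_reduced(counts, offsets, fit, j)
  names(p) <- rownames(counts)
  attr(p, "variable") <- as.integer(j)
  attr(p, "S") <- S
  p
}

# p-value matrix (genes x |S|) for all variables in S, one full fit
test_all_variables <- function(counts, ct, offsets, S,
                               dispersion = c("trended", "gene")) {
  S <- sort(unique(as.integer(S)))
  fit <- ql_full_fit(counts, ct, offsets, S, dispersion)
  P <- vapply(S, function(j) ql_test_reduced(counts, offsets, fit, j),
              numeric(nrow(counts)))
  P <- matrix(P, nrow = nrow(counts),
              dimnames = list(rownames(counts), ct$var_names[S]))
  attr(P, "S") <- S
  attr(P, "fit") <- fit
  P
}
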