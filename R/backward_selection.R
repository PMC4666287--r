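#' Backward selection of a common covariate set
#'
#' Starting from the model with all k variables, each iteration computes,
#' for every variable j still in the model, the vector of per-gene
#' quasi-likelihood p-values for dropping j; converts the primary factor's
#' p-values to q-values and records the number of discoveries R_l(alpha);
#' scores each variable's relevance ([relevance_p05()] or
#' [relevance_gks()]); and removes the least relevant variable. The
#' procedure stops when the primary factor itself is judged least relevant.
#' The selected model is the one in the elimination sequence with the most
#' discoveries (smallest iteration index on ties, i.e. the largest model).
#'
#' Ties in relevance are resolved by removing the variable with the larger
#' index (keeping earlier-declared variables); if the primary factor is
#' among the tied minima the procedure stops.
#'
#' @param counts Count matrix (genes x samples), already filtered.
#' @param ct A [covariate_table()]; variable 1 is the primary factor.
#' @param offsets Per-sample log offsets; default [compute_offsets()] on
#'   `counts`.
#' @param alpha FDR threshold for counting discoveries (default 0.05).
#' @param measure Relevance measure, `"p05"` (default) or `"gks"`.
#' @param dispersion Dispersion mode passed to the testing engine.
#' @param pvalue_fun Optional p-value engine, `function(S)` returning a
#'   genes x |S| matrix of p-values with columns in the order of `sort(S)`.
#'   Replaces the model-fitting engine (used for scripted algorithm tests
#'   and alternative inference back ends).
#' @param verbose Print per-iteration progress.
#' @return An object of class `selection_trace`: list with `iterations`
#'   (each with `ell`, `S`, `relevance`, `removed`, `R`, `m0`, `pvalues`),
#'   `L`, `R`, `ell_star`, `S_hat`, `alpha`, `measure`, `var_names`.
#' @export
backward_select <- function(counts, ct, offsets = NULL, alpha = 0.05,
                            measure = c("p05", "gks"),
                            dispersion = c("trended", "gene"),
                            pvalue_fun = NULL, verbose = FALSE) {
  measure <- match.arg(measure)
  dispersion <- match.arg(dispersion)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(pvalue_fun)) {
    counts <- validate_counts(counts)
    if (is.null(offsets)) offsets <- compute_offsets(counts)
  }
  k <- length(ct$var_names)
  S <- seq_len(k)
  iterations <- list()
  ell <- 0L
  repeat {
    ell <- ell + 1L
    P <- if (is.null(pvalue_fun)) {
      test_all_variables(counts, ct, offsets, S, dispersion)
    } else {
      pvalue_fun(S)
    }
    P <- as.matrix(P)
    if (ncol(P) != length(S))
      stop("p-value engine returned ", ncol(P), " columns for |S| = ",
           length(S))
    colnames(P) <- ct$var_names[S]

    p1 <- P[, 1L]
    m0 <- estimate_m0(p1)
    q1 <- qvalues(p1, m0)
    R <- count_rejections(q1, alpha)
    r <- vapply(seq_along(S), function(idx) relevance(P[, idx], measure),
                numeric(1L))
    names(r) <- ct$var_names[S]

    rmin <- min(r)
    tied <- S[r == rmin]
    if (length(tied) > 1L)
      message("iteration ", ell, ": relevance tie among ",
              paste(ct$var_names[tied], collapse = ", "),
              if (1L %in% tied) "; stopping (primary factor tied)"
              else "; removing the later-declared variable")
    jstar <- if (1L %in% tied) 1L else max(tied)

    iterations[[ell]] <- list(
      ell = ell, S = S, relevance = r,
      removed = if (jstar == 1L) NA_integer_ else jstar,
      R = R, m0 = m0, pvalues = P, qvalues_primary = q1)
    if (verbose)
      cat(sprintf("iter %d: |S| = %d, R(%g) = %d, least relevant = %s\n",
                  ell, length(S), alpha, R, ct$var_names[jstar]))
    if (jstar == 1L) break
    S <- setdiff(S, jstar)
  }
  Rvec <- vapply(iterations, `[[`, integer(1L), "R")
  ell_star <- which.max(Rvec)  # smallest maximizer
  structure(list(iterations = iterations, L = ell, R = Rvec,
                 ell_star = ell_star, S_hat = iterations[[ell_star]]$S,
                 alpha = alpha, measure = measure,
                 var_names = ct$var_names),
            class = "selection_trace")
}

#' Choose the model from a selection trace
#'
#' Returns the variable set of the iteration with the greatest number of
#' discoveries R_l(alpha); ties go to the smallest iteration index (the
#' largest model).
#'
#' @param trace A `selection_trace`.
#' @param alpha FDR threshold; default the trace's own. Recomputes R from
#'   the persisted primary-factor p-values if it differs.
#' @return The selected variable index set, with attribute `ell_star`.
#' @export
choose_model <- function(trace, alpha = trace$alpha) {
  stopifnot(inherits(trace, "selection_trace"))
  R <- if (identical(alpha, trace$alpha)) trace$R
       else vapply(trace$iterations, function(it)
         count_rejections(qvalues(it$pvalues[, 1L], it$m0), alpha),
         integer(1L))
  ell_star <- which.max(R)
  S <- trace$iterations[[ell_star]]$S
  attr(S, "ell_star") <- ell_star
  S
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Backward selection trace (", x$measure, " relevance, alpha = ",
      x$alpha, ")\n", sep = "")
  for (it in x$iterations) {
    rem <- if (is.na(it$removed)) paste0("stop (",
                                         x$var_names[1L], " least relevant)")
           else paste("removed", x$var_names[it$removed])
    cat(sprintf("  iter %d: |S| = %d, R = %d, %s\n",
                it$ell, length(it$S), it$R, rem))
  }
  cat("selected: iteration ", x$ell_star, ", variables { ",
      paste(x$var_names[x$S_hat], collapse = ", "), " }\n", sep = "")
  invisible(x)
}

#' Differential expression test under a fixed covariate set
#'
#' Fits each gene's NB log-linear model with the variables in `S_hat`,
#' tests the primary factor's coefficient block with the quasi-likelihood
#' F-test, and converts p-values to q-values. With `S_hat` from
#' [choose_model()], the p-values and q-values equal those stored at the
#' selected iteration of the trace.
#'
#' @inheritParams backward_select
#' @param S_hat Variable index set to control for (must contain 1).
#' @return A data.frame of class `de_result_table`: `gene`, `pvalue`,
#'   `qvalue`, primary coefficient estimate(s), `mean_count`, `converged`,
#'   `de` (q <= alpha); attributes `S`, `m0`, `d0`.
#' @export
de_test <- function(counts, ct, offsets = NULL, S_hat = 1L, alpha = 0.05,
                    dispersion = c("trended", "gene")) {
  counts <- validate_counts(counts)
  if (is.null(offsets)) offsets <- compute_offsets(counts)
  S_hat <- sort(unique(as.integer(S_hat)))
  fit <- ql_full_fit(counts, ct, offsets, S_hat, match.arg(dispersion))
  p <- ql_test_reduced(counts, offsets, fit, 1L)
  m0 <- estimate_m0(p)
  q <- qvalues(p, m0)
  est <- fit$full$beta[, fit$dm$blocks[["1"]], drop = FALSE]
  colnames(est) <- paste0("estimate_",
                          colnames(fit$dm$matrix)[fit$dm$blocks[["1"]]])
  out <- data.frame(gene = rownames(counts), pvalue = p, qvalue = as.numeric(q),
                    est, mean_count = rowMeans(counts),
                    converged = fit$full$converged,
                    de = !is.na(q) & q <= alpha,
                    row.names = NULL, check.names = FALSE)
  attr(out, "S") <- S_hat
  attr(out, "m0") <- m0
  attr(out, "d0") <- fit$shrink$d0
  class(out) <- c("de_result_table", "data.frame")
  out
}
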