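# fixtures are built in code; nothing is stored on disk

# small covariate table: binary primary "grp", continuous "x", categorical
# "blk" (3 levels), continuous "z"
make_ct <- function(n = 12, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(
      grp = rep(c("A", "B"), length.out = n),
      x = rnorm(n),
      blk = rep(c("u", "v", "w"), length.out = n),
      z = rnorm(n)
    )
    rownames(df) <- paste0("s", seq_len(n))
    covariate_table(df, primary = "grp",
                    types = c(grp = "categorical", x = "continuous",
                              blk = "categorical", z = "continuous"))
  })
}

# random small count fixture with ids
make_counts <- function(m = 6, n = 5, seed = 1, lambda = 20) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(m * n, lambda), m, n,
                     dimnames = list(paste0("g", seq_len(m)),
                                     paste0("s", seq_len(n))))
    counts
  })
}

# one simulated dataset (filtered, with offsets) for engine-level tests
make_sim <- function(m = 200, pi0 = 0.8, scenario = 1, seed = 1,
                     conf_mode = "confounded", n = 31) {
  withr::with_seed(seed, {
    ct <- sim_covariates(n, conf_mode = conf_mode)
    truth <- sim_parameters(m, pi0, ct, scenario = scenario)
    counts <- filter_genes(sim_counts(truth))
    list(ct = ct, truth = truth, counts = counts,
         offsets = compute_offsets(counts))
  })
}

# NB log-likelihood (dispersion omega, mean mu), for optimality oracles
nb_loglik <- function(y, mu, omega) {
  if (omega <= 0) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, mu = mu, size = 1 / omega, log = TRUE))
}

# scripted p-value engine: `scores` is a list keyed by iteration giving,
# for each variable index still in the model, the number of p-values to
# place at 1e-9 (these count toward p05 and produce that many q <= 0.05
# discoveries for the primary factor); remaining p-values sit at 0.9
scripted_pvalue_fun <- function(scores, m = 100) {
  ell <- 0L
  function(S) {
    ell <<- ell + 1L
    sc <- scores[[ell]]
    vapply(S, function(j) {
      r <- sc[[as.character(j)]]
      c(rep(1e-9, r), rep(0.9, m - r))
    }, numeric(m))
  }
}

# covariate table with k dummy variables for scripted-engine runs
dummy_ct <- function(k) {
  df <- data.frame(grp = rep(c("A", "B"), 4))
  for (j in seq_len(max(k, 2) - 1)) df[[paste0("v", j)]] <- rnorm(8)
  rownames(df) <- paste0("s", 1:8)
  ct <- suppressMessages(covariate_table(df, "grp"))
  if (k < length(ct$var_names)) {
    ct$var_names <- ct$var_names[seq_len(k)]
    ct$var_types <- ct$var_types[seq_len(k)]
    ct$data <- ct$data[, seq_len(k), drop = FALSE]
  }
  ct
}

# Hand-simulated backward-selection executions. Each case scripts, per
# iteration, the count of near-zero p-values for every variable still in
# the model (fixing both the p.05 relevance and, for the primary factor,
# the number of q <= 0.05 discoveries); `removed`, `L` and `ell_star` are
# the removal order, stopping point and selected iteration worked out by
# hand from the algorithm's definition.
scripted_cases <- function() {
  list(
    list(scores = list(c(`1` = 10, `2` = 40, `3` = 30, `4` = 5),
                       c(`1` = 15, `2` = 12, `3` = 35),
                       c(`1` = 20, `3` = 18),
                       c(`1` = 25)),
         removed = c(4, 2, 3), ell_star = 4),
    list(scores = list(c(`1` = 10, `2` = 40, `3` = 5),
                       c(`1` = 30, `2` = 20),
                       c(`1` = 12)),
         removed = c(3, 2), ell_star = 2),
    list(scores = list(c(`1` = 2, `2` = 40, `3` = 30)),
         removed = integer(0), ell_star = 1),
    list(scores = list(c(`1` = 30, `2` = 20, `3` = 20, `4` = 50),
                       c(`1` = 30, `2` = 20, `4` = 50),
                       c(`1` = 30, `4` = 20),
                       c(`1` = 30)),
         removed = c(3, 2, 4), ell_star = 1),
    list(scores = list(c(`1` = 15, `2` = 15, `3` = 40)),
         removed = integer(0), ell_star = 1),
    list(scores = list(c(`1` = 10, `2` = 30, `3` = 5),
                       c(`1` = 10, `2` = 8),
                       c(`1` = 10)),
         removed = c(3, 2), ell_star = 1),
    list(scores = list(c(`1` = 30, `2` = 40, `3` = 25),
                       c(`1` = 20, `2` = 15),
                       c(`1` = 10)),
         removed = c(3, 2), ell_star = 1),
    list(scores = list(c(`1` = 50, `2` = 7, `3` = 7, `4` = 7),
                       c(`1` = 50, `2` = 7, `3` = 7),
                       c(`1` = 50, `2` = 7),
                       c(`1` = 50)),
         removed = c(4, 3, 2), ell_star = 1),
    list(scores = list(c(`1` = 12, `2` = 30, `3` = 8),
                       c(`1` = 12, `2` = 12)),
         removed = c(3), ell_star = 1),
    list(scores = list(c(`1` = 6)),
         removed = integer(0), ell_star = 1, k = 1)
  )
}

# run one scripted case and check the trace against its hand simulation
check_scripted_case <- function(case) {
  k <- if (!is.null(case$k)) case$k else length(case$scores[[1]])
  ct <- dummy_ct(k)
  tr <- suppressMessages(backward_select(
    counts = NULL, ct = ct, alpha = 0.05,
    pvalue_fun = scripted_pvalue_fun(case$scores)))
  got_removed <- vapply(tr$iterations, `[[`, integer(1), "removed")
  testthat::expect_identical(tr$L, length(case$scores))
  testthat::expect_identical(got_removed[!is.na(got_removed)],
                             as.integer(case$removed))
  testthat::expect_true(is.na(got_removed[tr$L]))
  testthat::expect_identical(tr$ell_star, as.integer(case$ell_star))
  testthat::expect_identical(tr$R,
    vapply(seq_len(tr$L), function(l)
      as.integer(case$scores[[l]][["1"]]), integer(1)))
  testthat::expect_identical(tr$ell_star, which.max(tr$R))
  testthat::expect_identical(tr$S_hat, tr$iterations[[tr$ell_star]]$S)
  invisible(tr)
}
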