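#' Default effect-size scheme for the simulation framework
#'
#' The distributions from which gene-level model parameters are drawn.
#' Intercepts are N(3, 1) on the natural-log scale (median baseline mean
#' ~20 reads before depth scaling); covariate coefficients are N(0, 0.25^2)
#' on blocks inside a gene's relevant set; primary-factor coefficients of
#' DE genes are N(0, 0.5^2) excluding the dead zone (-0.1, 0.1), so
#' differential expression is unambiguous; dispersions are log-normal with
#' median 0.1; per-sample depth factors are uniform(0.8, 1.25) times a
#' common depth constant of 2.
#'
#' @param intercept_mean,intercept_sd Intercept distribution (log scale).
#' @param cov_effect_sd SD of covariate-block coefficients.
#' @param de_effect_sd SD of primary-factor coefficients for DE genes.
#' @param de_min_effect Half-width of the excluded dead zone around 0.
#' @param omega_meanlog,omega_sdlog Log-normal dispersion parameters.
#' @param depth Common sequencing-depth constant multiplying the
#'   uniform(depth_range) per-sample factors.
#' @param depth_range Range of per-sample depth factors.
#' @return A list of scheme parameters.
#' @export
sim_scheme <- function(intercept_mean = 3, intercept_sd = 1,
                       cov_effect_sd = 0.25, de_effect_sd = 0.5,
                       de_min_effect = 0.1,
                       omega_meanlog = log(0.1), omega_sdlog = 0.5,
                       depth = 2, depth_range = c(0.8, 1.25)) {
  as.list(environment())
}

#' Simulate a covariate table
#'
#' Generates n samples with: a two-level primary factor `group` split as
#' evenly as possible; a continuous covariate `conf` associated with the
#' primary factor (`conf = delta * indicator + N(0, 1)`); `n_continuous`
#' standard normal covariates `cov1, cov2, ...`; `n_categorical`
#' categorical covariates `blockA, ...` uniform over `cat_levels` levels
#' (redrawn until every level is observed); and `n_noise` standard normal
#' covariates `noise1, ...` intended to be irrelevant. In
#' `conf_mode = "orthogonal"` the confounded covariate is centered within
#' primary-factor groups after generation (consuming no extra random
#' numbers, so runs with the two modes are otherwise identical given the
#' same RNG state); `"none"` sets delta to 0.
#'
#' @param n Number of samples (>= 4).
#' @param n_continuous,n_categorical,n_noise Covariate counts.
#' @param cat_levels Number of levels per categorical covariate.
#' @param delta Association strength of `conf` with the primary factor.
#' @param conf_mode `"confounded"`, `"orthogonal"`, or `"none"`.
#' @return A [covariate_table()] with a `roles` attribute tagging each
#'   variable as primary / confounded / covariate / noise.
#' @export
sim_covariates <- function(n = 31, n_continuous = 2, n_categorical = 1,
                           cat_levels = 4, n_noise = 1, delta = 3,
                           conf_mode = c("confounded", "orthogonal", "none")) {
  conf_mode <- match.arg(conf_mode)
  if (n < 4) stop("need n >= 4")
  if (conf_mode == "none") delta <- 0
  n1 <- ceiling(n / 2)
  group <- factor(rep(c("A", "B"), c(n1, n - n1)))
  df <- data.frame(group = group)
  roles <- "primary"

  df$conf <- delta * (group == "B") + stats::rnorm(n)
  roles <- c(roles, "confounded")
  for (i in seq_len(n_continuous)) {
    df[[paste0("cov", i)]] <- stats::rnorm(n)
    roles <- c(roles, "covariate")
  }
  for (i in seq_len(n_categorical)) {
    if (cat_levels > n) stop("more categorical levels than samples")
    repeat {
      lv <- sample(LETTERS[seq_len(cat_levels)], n, replace = TRUE)
      if (length(unique(lv)) == cat_levels) break
    }
    df[[paste0("block", LETTERS[i])]] <- lv
    roles <- c(roles, "covariate")
  }
  for (i in seq_len(n_noise)) {
    df[[paste0("noise", i)]] <- stats::rnorm(n)
    roles <- c(roles, "noise")
  }
  if (conf_mode == "orthogonal")
    df$conf <- center_within_groups(df$conf, group)
  rownames(df) <- sprintf("s%02d", seq_len(n))

  types <- stats::setNames(
    ifelse(vapply(df, is.numeric, logical(1L)), "continuous", "categorical"),
    colnames(df))
  ct <- covariate_table(df, primary = "group", types = types)
  attr(ct, "roles") <- roles
  ct
}

#' Center a vector within groups
#'
#' Subtracts each group's mean, making the result orthogonal to every
#' group indicator column (and to the intercept).
#'
#' @param x Numeric vector.
#' @param groups Group labels, same length; every group non-empty.
#' @return The within-group centered vector.
#' @export
center_within_groups <- function(x, groups) {
  stopifnot(length(x) == length(groups))
  x - stats::ave(x, groups)
}

# default relevant variable sets by scenario, from the roles attribute
default_relevant_sets <- function(ct, scenario) {
  roles <- attr(ct, "roles")
  if (is.null(roles)) stop("covariate table carries no roles; give relevant_sets")
  covs <- which(roles == "covariate")
  conf <- which(roles == "confounded")
  if (scenario == 1) {
    list(sort(c(1L, covs)))
  } else {
    # nested chain: union (with the confounded covariate) down to primary+1
    sets <- list(sort(c(1L, conf, covs)), sort(c(1L, covs)))
    while (length(covs) > 1L) {
      covs <- covs[-1L]
      sets <- c(sets, list(sort(c(1L, covs))))
    }
    sets
  }
}

#' Draw gene-level simulation parameters
#'
#' Builds the ground truth for one simulated dataset: per-gene coefficient
#' vectors on the full design, NB dispersions, relevant covariate sets, and
#' EE/DE labels. A fraction `pi0` of genes are equivalently expressed
#' (primary-factor block exactly zero); the rest draw primary-factor
#' coefficients outside a dead zone so that differential expression is
#' well defined. Covariate coefficients are nonzero only on blocks inside
#' the gene's relevant set. Scenario 1 uses one common relevant set for
#' all genes; scenarios 2 and 3 partition genes equally across a nested
#' chain of sets whose largest member includes the confounded covariate.
#'
#' @param m Number of genes.
#' @param pi0 Proportion of EE genes, in (0, 1].
#' @param ct A [sim_covariates()] table (or any covariate_table plus
#'   explicit `relevant_sets`).
#' @param scenario 1 (common set), 2 (nested sets, confounded covariate),
#'   or 3 (as 2; pair it with `conf_mode = "orthogonal"` covariates).
#' @param relevant_sets Optional list of variable index sets overriding the
#'   scenario defaults.
#' @param scheme Effect-size scheme from [sim_scheme()].
#' @return A list of class `simulation_truth`: `beta` (genes x p, full
#'   design), `omega`, `relevant_sets`, `set_index` (per gene),
#'   `is_DE`, `pi0`, `ct`, `design`, `offsets`, `gene_ids`.
#' @export
sim_parameters <- function(m, pi0, ct, scenario = 1, relevant_sets = NULL,
                           scheme = sim_scheme()) {
  stopifnot(pi0 > 0, pi0 <= 1, m >= 1)
  if (is.null(relevant_sets))
    relevant_sets <- default_relevant_sets(ct, scenario)
  dm <- design_matrix(ct, seq_along(ct$var_names))
  X <- dm$matrix
  n <- nrow(X); p <- ncol(X)

  n_ee <- round(pi0 * m)
  if (abs(pi0 * m - n_ee) > 1e-8)
    warning("pi0 * m is not an integer; using ", n_ee, " EE genes")
  is_DE <- rep(FALSE, m)
  is_DE[sample.int(m, m - n_ee)] <- TRUE

  set_index <- if (scenario == 1) rep(1L, m)
               else sort(rep_len(seq_along(relevant_sets), m))

  beta <- matrix(0, m, p, dimnames = list(NULL, colnames(X)))
  beta[, 1L] <- stats::rnorm(m, scheme$intercept_mean, scheme$intercept_sd)
  prim_cols <- dm$blocks[["1"]]
  for (g in seq_len(m)) {
    rel <- relevant_sets[[set_index[g]]]
    for (j in setdiff(rel, 1L)) {
      cols <- dm$blocks[[as.character(j)]]
      beta[g, cols] <- stats::rnorm(length(cols), 0, scheme$cov_effect_sd)
    }
    if (is_DE[g]) {
      eff <- stats::rnorm(length(prim_cols), 0, scheme$de_effect_sd)
      small <- abs(eff) < scheme$de_min_effect
      eff[small] <- sign(eff[small] + (eff[small] == 0)) *
        (scheme$de_min_effect +
           abs(stats::rnorm(sum(small), 0, scheme$de_effect_sd)))
      beta[g, prim_cols] <- eff
    }
  }

  offsets <- log(scheme$depth *
                   stats::runif(n, scheme$depth_range[1L],
                                scheme$depth_range[2L]))
  names(offsets) <- ct$sample_ids
  omega <- stats::rlnorm(m, scheme$omega_meanlog, scheme$omega_sdlog)

  structure(list(beta = beta, omega = omega,
                 relevant_sets = relevant_sets, set_index = set_index,
                 is_DE = is_DE, pi0 = pi0, ct = ct, design = X,
                 blocks = dm$blocks, offsets = offsets,
                 gene_ids = sprintf("g%05d", seq_len(m)),
                 scheme = scheme, scenario = scenario),
            class = "simulation_truth")
}

#' Simulate read counts from a simulation truth
#'
#' Draws independent negative binomial counts with
#' `log(mean) = offset + x' beta` and variance `mu + omega * mu^2`
#' (Poisson for `omega = 0`).
#'
#' @param truth A [sim_parameters()] object.
#' @return Integer count matrix (genes x samples) with ids.
#' @export
sim_counts <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  X <- truth$design
  m <- nrow(truth$beta); n <- nrow(X)
  log_mu <- truth$beta %*% t(X) +
    matrix(truth$offsets, m, n, byrow = TRUE)
  if (any(log_mu > 30)) {
    g <- which(apply(log_mu > 30, 1L, any))[1L]
    stop("log mean exceeds 30 for gene ", truth$gene_ids[g],
         "; effect sizes too extreme")
  }
  mu <- exp(log_mu)
  size <- rep(ifelse(truth$omega > 0, 1 / truth$omega, Inf), n)
  y <- numeric(m * n)
  nb <- is.finite(size)
  y[nb] <- stats::rnbinom(sum(nb), mu = mu[nb], size = size[nb])
  y[!nb] <- stats::rpois(sum(!nb), lambda = mu[!nb])
  counts <- matrix(as.integer(y), m, n,
                   dimnames = list(truth$gene_ids, truth$ct$sample_ids))
  counts
}

# trapezoidal partial AUC of the ROC for scores (higher = more DE-like),
# ties handled as diagonal segments, restricted to FPR <= fpr_max
partial_auc <- function(score, is_de, fpr_max = 0.05) {
  ok <- is.finite(score)
  score <- score[ok]; is_de <- is_de[ok]
  nD <- sum(is_de); nE <- sum(!is_de)
  if (nD == 0L || nE == 0L) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  lab <- is_de[ord]
  sc <- score[ord]
  ends <- cumsum(rle(sc)$lengths)
  fpr <- c(0, cumsum(!lab)[ends] / nE)
  tpr <- c(0, cumsum(lab)[ends] / nD)
  if (fpr[length(fpr)] < fpr_max) fpr_max <- fpr[length(fpr)]
  # interpolate tpr at fpr_max and integrate below it
  upper <- which(fpr >= fpr_max)[1L]
  if (fpr[upper] > fpr_max) {
    lo <- upper - 1L
    t_at <- tpr[lo] + (tpr[upper] - tpr[lo]) *
      (fpr_max - fpr[lo]) / (fpr[upper] - fpr[lo])
    fpr <- c(fpr[seq_len(lo)], fpr_max)
    tpr <- c(tpr[seq_len(lo)], t_at)
  } else {
    fpr <- fpr[seq_len(upper)]
    tpr <- tpr[seq_len(upper)]
  }
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Score differential expression calls against simulation truth
#'
#' Computes the realized false discovery proportion `V / max(R, 1)`, the
#' number of true positives, and the partial area under the ROC curve for
#' false positive rates up to 0.05 (scores `1 - p`, ties averaged). A gene
#' counts as a false discovery iff its own `is_DE` label is FALSE,
#' regardless of which model was fitted.
#'
#' @param de A [de_test()] result (or data.frame with `gene`, `pvalue`,
#'   `qvalue`).
#' @param truth The matching [sim_parameters()] object.
#' @param alpha FDR threshold for calls (`q <= alpha`).
#' @return A one-row data.frame: `fdp`, `ntp`, `pauc`, `discoveries`,
#'   `n_genes`.
#' @export
evaluate_calls <- function(de, truth, alpha = 0.05) {
  idx <- match(de$gene, truth$gene_ids)
  if (anyNA(idx)) stop("DE results contain genes absent from the truth")
  is_de_true <- truth$is_DE[idx]
  called <- !is.na(de$qvalue) & de$qvalue <= alpha
  R <- sum(called)
  V <- sum(called & !is_de_true)
  data.frame(fdp = V / max(R, 1L), ntp = sum(called & is_de_true),
             pauc = partial_auc(1 - de$pvalue, is_de_true),
             discoveries = R, n_genes = nrow(de))
}

# oracle analysis: each gene tested under its own true relevant set
oracle_de <- function(counts, ct, offsets, truth, alpha) {
  idx <- match(rownames(counts), truth$gene_ids)
  set_index <- truth$set_index[idx]
  p <- rep(NA_real_, nrow(counts))
  for (s in unique(set_index)) {
    rows <- which(set_index == s)
    fit <- ql_full_fit(counts[rows, , drop = FALSE], ct, offsets,
                       truth$relevant_sets[[s]])
    p[rows] <- ql_test_reduced(counts[rows, , drop = FALSE], offsets,
                               fit, 1L)
  }
  q <- qvalues(p)
  out <- data.frame(gene = rownames(counts), pvalue = p,
                    qvalue = as.numeric(q),
                    de = !is.na(q) & q <= alpha, row.names = NULL)
  out
}

#' Run a simulation scenario
#'
#' Generates replicate datasets under one of the three covariate-structure
#' scenarios, analyzes each with the requested strategies, and scores them
#' against the truth. Strategies: `backward_p05` / `backward_gks` (backward
#' selection with either relevance measure), `full` (all variables),
#' `primary_only`, and `oracle` (each gene's true relevant set; in
#' scenarios 2-3 applied per gene group). Each replicate is filtered with
#' the default [filter_genes()] rule and normalized with
#' [compute_offsets()] before analysis. Replicate seeds are drawn once
#' from `seed`, so scenario 2 and scenario 3 runs with the same `seed`
#' are paired: they share all randomness except the within-group centering
#' of the confounded covariate.
#'
#' @param scenario 1, 2, or 3.
#' @param pi0 Proportion(s) of EE genes; a vector runs a grid.
#' @param reps Replicates per `pi0` value.
#' @param m Genes per dataset.
#' @param strategies Character vector of analysis strategies.
#' @param alpha FDR threshold.
#' @param seed Integer seed governing all randomness.
#' @param n Samples per dataset.
#' @param covariate_config Extra arguments to [sim_covariates()].
#' @param scheme Effect-size scheme from [sim_scheme()].
#' @param verbose Print progress.
#' @return List of class `scenario_result`: `replicates` (one row per
#'   replicate x strategy: fdp, ntp, pauc, discoveries, model size,
#'   covers_truth), `summary` (means and standard errors by pi0 and
#'   strategy), and `config`.
#' @export
run_scenario <- function(scenario = 1, pi0 = 0.9, reps = 10, m = 1000,
                         strategies = c("backward_p05", "full",
                                        "primary_only"),
                         alpha = 0.05, seed = 1, n = 31,
                         covariate_config = list(), scheme = sim_scheme(),
                         verbose = FALSE) {
  known <- c("backward_p05", "backward_gks", "full", "primary_only",
             "oracle")
  bad <- setdiff(strategies, known)
  if (length(bad)) stop("unknown strategy: ", paste(bad, collapse = ", "))
  stopifnot(scenario %in% 1:3)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, reps * length(pi0)),
                      nrow = reps)

  conf_mode <- if (scenario == 3) "orthogonal" else "confounded"
  rows <- list()
  for (ip in seq_along(pi0)) {
    for (r in seq_len(reps)) {
      set.seed(rep_seeds[r, ip])
      ct <- do.call(sim_covariates,
                    c(list(n = n, conf_mode = conf_mode), covariate_config))
      truth <- sim_parameters(m, pi0[ip], ct, scenario = scenario,
                              scheme = scheme)
      counts <- sim_counts(truth)
      counts <- filter_genes(counts)
      offsets <- compute_offsets(counts)
      k <- length(ct$var_names)
      union_set <- sort(unique(unlist(truth$relevant_sets)))

      for (st in strategies) {
        covers <- NA
        n_vars <- NA_integer_
        de <- switch(st,
          backward_p05 = ,
          backward_gks = {
            meas <- if (st == "backward_gks") "gks" else "p05"
            tr <- backward_select(counts, ct, offsets, alpha = alpha,
                                  measure = meas)
            it <- tr$iterations[[tr$ell_star]]
            covers <- all(union_set %in% tr$S_hat)
            n_vars <- length(tr$S_hat)
            data.frame(gene = rownames(counts),
                       pvalue = it$pvalues[, 1L],
                       qvalue = as.numeric(it$qvalues_primary),
                       row.names = NULL)
          },
          full = {
            n_vars <- k
            de_test(counts, ct, offsets, S_hat = seq_len(k), alpha = alpha)
          },
          primary_only = {
            n_vars <- 1L
            de_test(counts, ct, offsets, S_hat = 1L, alpha = alpha)
          },
          oracle = {
            n_vars <- NA_integer_
            oracle_de(counts, ct, offsets, truth, alpha)
          })
        ev <- evaluate_calls(de, truth, alpha)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(scenario = scenario, pi0 = pi0[ip], rep = r,
                     seed = rep_seeds[r, ip], strategy = st,
                     n_model_vars = n_vars, covers_truth = covers),
          ev)
        if (verbose)
          cat(sprintf("scenario %d pi0=%.2f rep %d %s: fdp=%.3f ntp=%d\n",
                      scenario, pi0[ip], r, st, ev$fdp, ev$ntp))
      }
    }
  }
  replicates <- do.call(rbind, rows)
  se <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
  summary <- do.call(rbind, lapply(
    split(replicates, list(replicates$pi0, replicates$strategy),
          drop = TRUE),
    function(d) data.frame(
      scenario = scenario, pi0 = d$pi0[1L], strategy = d$strategy[1L],
      reps = nrow(d),
      fdr = mean(d$fdp), fdr_se = se(d$fdp),
      ntp = mean(d$ntp), ntp_se = se(d$ntp),
      pauc = mean(d$pauc), pauc_se = se(d$pauc),
      covers_truth = mean(d$covers_truth))))
  rownames(summary) <- NULL
  structure(list(replicates = replicates, summary = summary,
                 config = list(scenario = scenario, pi0 = pi0, reps = reps,
                               m = m, n = n, alpha = alpha, seed = seed,
                               strategies = strategies,
                               covariate_config = covariate_config,
                               scheme = scheme)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Simulation scenario", x$config$scenario, "-", x$config$reps,
      "replicates x pi0 in {", paste(x$config$pi0, collapse = ", "),
      "}, m =", x$config$m, "genes\n")
  print(x$summary, digits = 3)
  invisible(x)
}
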