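test_that("within-group centering zeroes group means and is a projection", {
  expect_equal(center_within_groups(c(1, 2, 3, 4), c("A", "A", "B", "B")),
               c(-0.5, 0.5, -0.5, 0.5))
  x <- c(-1, 1, 2, -2)
  expect_equal(center_within_groups(x, c("A", "A", "B", "B")), x)

  set.seed(20)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    g <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(g)) < 3) next
    xc <- center_within_groups(rnorm(n), g)
    for (l in unique(g))
      expect_lt(abs(sum(xc[g == l])), 1e-10)
  }
})

test_that("simulated covariates have the declared structure", {
  set.seed(2)
  ct <- sim_covariates(31)
  expect_identical(table(ct$data$group), table(factor(rep(c("A", "B"), c(16, 15)))))
  expect_identical(ct$var_names,
                   c("group", "conf", "cov1", "cov2", "blockA", "noise1"))
  expect_identical(attr(ct, "roles"),
                   c("primary", "confounded", "covariate", "covariate",
                     "covariate", "noise"))
  expect_equal(nlevels(ct$data$blockA), 4)

  # orthogonal mode: conf sums to zero within each group
  cto <- sim_covariates(31, conf_mode = "orthogonal")
  for (l in c("A", "B"))
    expect_lt(abs(sum(cto$data$conf[cto$data$group == l])), 1e-12)
})

test_that("with delta = 0 the confounded covariate is independent of the factor", {
  set.seed(6)
  rej <- replicate(1000, {
    ct <- sim_covariates(20, conf_mode = "none")
    t.test(conf ~ group, data = ct$data)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("parameter draws honor pi0, relevant sets, and the EE definition", {
  set.seed(3)
  ct <- sim_covariates(31)
  truth <- sim_parameters(5000, 0.8, ct, scenario = 1)
  expect_equal(sum(!truth$is_DE), 4000)
  prim <- truth$blocks[["1"]]
  expect_true(all(truth$beta[!truth$is_DE, prim] == 0))
  expect_true(all(abs(truth$beta[truth$is_DE, prim]) >= 0.1))
  # scenario 1: no gene loads on conf or noise
  off_set <- unlist(truth$blocks[as.character(c(2, 6))])
  expect_true(all(truth$beta[, off_set] == 0))

  t2 <- sim_parameters(5000, 0.8, ct, scenario = 2)
  expect_equal(as.integer(table(t2$set_index)), rep(1250L, 4))
  expect_length(t2$relevant_sets, 4)
  # the chain is nested and its head contains the confounded covariate
  for (i in 2:4)
    expect_true(all(t2$relevant_sets[[i]] %in% t2$relevant_sets[[i - 1]]))
  expect_true(2 %in% t2$relevant_sets[[1]])
  # genes outside a set have zero coefficients there
  g_last <- which(t2$set_index == 4)
  cols_excluded <- unlist(t2$blocks[as.character(setdiff(t2$relevant_sets[[1]],
                                                         t2$relevant_sets[[4]]))])
  expect_true(all(t2$beta[g_last, cols_excluded] == 0))

  expect_warning(sim_parameters(10, 0.55, ct), "not an integer")
})

test_that("count simulation follows the NB mean-variance structure", {
  set.seed(44)
  ct <- sim_covariates(10, n_continuous = 1, n_categorical = 1,
                       cat_levels = 2, n_noise = 1)
  truth <- sim_parameters(1000, 1, ct, scenario = 1)
  truth$omega[] <- 0
  truth$beta[, -1] <- 0
  truth$beta[, 1] <- 3
  truth$offsets[] <- 0
  counts <- sim_counts(truth)
  disp_index <- var(as.numeric(counts)) / mean(counts)  # 10,000 Poisson draws
  expect_gt(disp_index, 0.95)
  expect_lt(disp_index, 1.05)

  # doubling the offsets (log 2) doubles the sample means
  t2 <- truth
  t2$offsets <- truth$offsets + log(2)
  set.seed(1); c1 <- sim_counts(truth)
  set.seed(1); c2 <- sim_counts(t2)
  expect_equal(mean(c2) / mean(c1), 2, tolerance = 0.05)

  # reproducibility
  set.seed(9); a <- sim_counts(truth)
  set.seed(9); b <- sim_counts(truth)
  expect_identical(a, b)

  # overflow guard names the gene
  t3 <- truth
  t3$beta[5, 1] <- 40
  expect_error(sim_counts(t3), "g00005")
})

test_that("evaluation metrics match their definitions and a null closed form", {
  ct <- sim_covariates(8, n_continuous = 1, n_categorical = 1,
                       cat_levels = 2, n_noise = 1)
  set.seed(1)
  truth <- sim_parameters(100, 0.5, ct)
  # perfect separation: DE genes get tiny p, EE genes get large p
  p <- ifelse(truth$is_DE, 1e-8, 0.9)
  de <- data.frame(gene = truth$gene_ids, pvalue = p,
                   qvalue = ifelse(truth$is_DE, 1e-6, 0.9))
  ev <- evaluate_calls(de, truth, 0.05)
  expect_equal(ev$fdp, 0)
  expect_equal(ev$ntp, sum(truth$is_DE))
  expect_equal(ev$pauc, 0.05)

  # no rejections
  de0 <- transform(de, qvalue = 1)
  ev0 <- evaluate_calls(de0, truth, 0.05)
  expect_equal(ev0$fdp, 0)
  expect_equal(ev0$ntp, 0)

  # misalignment errors
  de_bad <- de; de_bad$gene[1] <- "nope"
  expect_error(evaluate_calls(de_bad, truth, 0.05), "absent")

  # random scores: mean PAUC ~ 0.05^2 / 2
  set.seed(55)
  m <- 2000
  lab <- rep(c(TRUE, FALSE), m / 2)
  paucs <- replicate(200, covsel:::partial_auc(runif(m), lab))
  null_val <- 0.05^2 / 2
  se <- sd(paucs) / sqrt(200)
  expect_lt(abs(mean(paucs) - null_val), 3 * se + 1e-5)
})

test_that("partial AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  lab <- rep(c(TRUE, FALSE), 150)
  score <- rnorm(300) + lab
  ours <- covsel:::partial_auc(score, lab, 0.05)
  ref <- suppressMessages(
    pROC::auc(pROC::roc(lab, score, direction = "<"),
              partial.auc = c(1, 0.95),
              partial.auc.focus = "specificity"))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})

test_that("scenario runs emit well-formed replicate and summary tables", {
  res <- run_scenario(1, pi0 = 0.8, reps = 2, m = 100,
                      strategies = c("backward_p05", "backward_gks", "full",
                                     "primary_only", "oracle"),
                      seed = 3)
  expect_s3_class(res, "scenario_result")
  expect_equal(nrow(res$replicates), 2 * 5)
  expect_true(all(res$replicates$fdp >= 0 & res$replicates$fdp <= 1))
  expect_true(all(res$replicates$ntp <= sum(res$replicates$n_genes)))
  expect_true(all(c("fdr", "ntp", "pauc") %in% names(res$summary)))
  expect_error(run_scenario(1, strategies = "bogus"), "unknown strategy")
})

test_that("scenario 3 shares all randomness with scenario 2 except the centering", {
  seed <- 402
  set.seed(seed); ct2 <- sim_covariates(31, conf_mode = "confounded")
  set.seed(seed); ct3 <- sim_covariates(31, conf_mode = "orthogonal")
  expect_equal(ct3$data$conf, center_within_groups(ct2$data$conf,
                                                   ct2$data$group))
  same <- setdiff(colnames(ct2$data), "conf")
  expect_identical(ct2$data[same], ct3$data[same])
})

test_that("the oracle is not systematically beaten in power by backward selection", {
  res <- run_scenario(1, pi0 = 0.7, reps = 6, m = 300,
                      strategies = c("backward_p05", "oracle"), seed = 31)
  s <- res$summary
  ntp_b <- s$ntp[s$strategy == "backward_p05"]
  ntp_o <- s$ntp[s$strategy == "oracle"]
  se_o <- s$ntp_se[s$strategy == "oracle"]
  expect_gte(ntp_o, ntp_b - 2 * se_o)
})
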