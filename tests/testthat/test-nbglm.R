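test_that("Poisson-limit fits recover closed-form MLEs and the offset identity", {
  X <- matrix(1, 3, 1)
  f <- fit_nb_glm(c(2, 4, 6), X, offsets = rep(0, 3), omega = 0)
  expect_equal(unname(f$beta), log(4), tolerance = 1e-8)
  expect_true(f$converged)

  # adding c to all offsets shifts the intercept by -c only
  set.seed(4)
  n <- 10
  X2 <- cbind(1, rnorm(n), rep(0:1, 5))
  y <- rpois(n, 20)
  f1 <- fit_nb_glm(y, X2, offsets = rep(0, n), omega = 0.1)
  f2 <- fit_nb_glm(y, X2, offsets = rep(1.7, n), omega = 0.1)
  expect_equal(f2$beta[1], f1$beta[1] - 1.7, tolerance = 1e-7)
  expect_equal(f2$beta[-1], f1$beta[-1], tolerance = 1e-7)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-7)
})

test_that("returned coefficients are local optima of the NB likelihood", {
  set.seed(11)
  wins <- TRUE
  for (i in 1:50) {
    n <- 8; p <- 3
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    o <- rnorm(n, 0, 0.2)
    y <- rnbinom(n, mu = exp(o + drop(X %*% c(2.5, 0.4, -0.3))), size = 5)
    f <- fit_nb_glm(y, X, o, omega = 0.2)
    ll_hat <- nb_loglik(y, f$mu, 0.2)
    pert <- matrix(rnorm(1000 * p, 0, 0.05), 1000)
    ll_pert <- apply(pert, 1, function(d) {
      nb_loglik(y, exp(pmin(o + drop(X %*% (f$beta + d)), 30)), 0.2)
    })
    wins <- wins && all(ll_hat >= ll_pert - 1e-8)
  }
  expect_true(wins)
})

test_that("omega = 0 fits agree with an independent Poisson IRLS", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n))
    o <- rnorm(n, 0, 0.3)
    y <- rpois(n, exp(o + drop(X %*% c(2, 0.5, -0.4))))
    ours <- fit_nb_glm(y, X, o, omega = 0)
    ref <- suppressWarnings(
      glm.fit(X, y, offset = o, family = poisson()))
    expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(ours$deviance, ref$deviance, tolerance = 1e-6)
  }
})

test_that("fixed-dispersion NB fits agree with glm.fit under the matching family", {
  skip_if_not_installed("MASS")
  set.seed(31)
  for (i in 1:20) {
    n <- 15
    X <- cbind(1, rnorm(n))
    o <- rep(log(2), n)
    omega <- 0.25
    y <- rnbinom(n, mu = exp(o + drop(X %*% c(3, 0.6))), size = 1 / omega)
    ours <- fit_nb_glm(y, X, o, omega = omega)
    ref <- suppressWarnings(
      glm.fit(X, y, offset = o,
              family = MASS::negative.binomial(theta = 1 / omega)))
    expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-4)
    expect_equal(ours$deviance, ref$deviance, tolerance = 1e-5)
  }
})

test_that("moment dispersion floors at Poisson and recovers a known omega", {
  X <- matrix(1, 4, 1)
  expect_equal(estimate_nb_dispersion(c(5, 5, 5, 5), X, rep(0, 4)), 0)
  # variance <= mean data
  expect_equal(estimate_nb_dispersion(c(9, 10, 10, 11), X, rep(0, 4)), 0)

  set.seed(5)
  y <- rnbinom(200, mu = 50, size = 10)  # omega = 0.1
  om <- estimate_nb_dispersion(y, matrix(1, 200, 1), rep(0, 200))
  expect_lt(abs(om - 0.1), 0.05)
})

test_that("LR statistics are deviance gaps with the dropped block's df", {
  set.seed(8)
  n <- 6
  X <- cbind(1, rep(0:1, 3))
  o <- rep(0, n)
  y <- rpois(n, 10)
  full <- fit_nb_glm(y, X, o, omega = 0)
  red <- fit_nb_glm(y, X[, 1, drop = FALSE], o, omega = 0)
  lrt <- lrt_stat(full, red, df1 = 1)
  # closed-form Poisson deviance oracle: group means vs grand mean
  dev_of <- function(mu) 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  g <- X[, 2]
  mu_full <- ave(y, g)
  oracle <- dev_of(rep(mean(y), n)) - dev_of(mu_full)
  expect_equal(lrt$stat, oracle, tolerance = 1e-7)
  expect_identical(lrt$df1, 1L)

  expect_equal(lrt_stat(full, full, 1)$stat, 0)
  expect_identical(lrt_stat(full, red, 2)$df1, 2L)
})

test_that("nested designs never increase deviance", {
  set.seed(13)
  ok <- TRUE
  for (i in 1:20) {
    n <- 12
    X <- cbind(1, rnorm(n), rep(0:1, 6))
    o <- rnorm(n, 0, 0.1)
    y <- rnbinom(n, mu = exp(o + 2.5), size = 8)
    omega <- 0.15
    d_full <- fit_nb_glm(y, X, o, omega)$deviance
    d_red <- fit_nb_glm(y, X[, -3], o, omega)$deviance
    ok <- ok && (d_full <= d_red + 1e-8)
  }
  expect_true(ok)
})
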