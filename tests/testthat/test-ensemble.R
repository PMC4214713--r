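# Conjugate Gaussian ensemble: closed forms, sequential consistency,
# significance testing and BH decisions.

test_that("posterior matches closed forms with no data and one observation", {
  p0 <- fit_posterior(NULL, sigma = 2, b = 0.25, p = 3)
  expect_equal(p0$mu, rep(0, 3))
  expect_equal(posterior_covariance(p0), diag(4, 3))
  expect_equal(p0$n_obs, 0L)

  # X = [1 0], y = 1, sigma = b = 1: Gamma = diag(1/2, 1), mu = (1/2, 0)
  p1 <- fit_posterior(list(X = matrix(c(1, 0), 1), y = 1), sigma = 1, b = 1)
  expect_equal(posterior_covariance(p1), diag(c(1 / 2, 1)))
  expect_equal(p1$mu, c(1 / 2, 0))

  # data-frame input with a y column is equivalent
  df <- data.frame(x1 = 1, x2 = 0, y = 1)
  p1b <- fit_posterior(df, sigma = 1, b = 1)
  expect_equal(p1b$mu, p1$mu)
})

test_that("posterior mean equals an independent ridge solve", {
  set.seed(41)
  X <- matrix(runif(5 * 3, -1, 1), 5, 3)
  beta <- c(1, -2, 0)
  y <- as.vector(X %*% beta)
  sigma <- 0.1; b <- 1e-4
  post <- fit_posterior(list(X = X, y = y), sigma, b)
  # naive ridge oracle: (X'X + sigma^2 b I)^{-1} X'y
  oracle <- solve(crossprod(X) + sigma^2 * b * diag(3), crossprod(X, y))
  expect_equal(post$mu, as.vector(oracle), tolerance = 1e-8)
  expect_true(max(abs(post$mu - beta)) < 0.05)
})

test_that("sequential batch updates reproduce the one-shot fit", {
  set.seed(7)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  oneshot <- fit_posterior(list(X = X, y = y), sigma = 0.5, b = 0.3)
  # arbitrary partitions of the rows
  for (cut in list(c(7, 20), c(1, 20), c(13, 17, 20))) {
    post <- fit_posterior(NULL, sigma = 0.5, b = 0.3, p = 10)
    lo <- 1L
    for (hi in cut) {
      post <- update_posterior(post, X[lo:hi, , drop = FALSE], y[lo:hi])
      lo <- hi + 1L
    }
    expect_equal(post$n_obs, 20L)
    expect_lt(norm(posterior_covariance(post) - posterior_covariance(oneshot),
                   "F") / norm(posterior_covariance(oneshot), "F"), 1e-8)
    expect_equal(post$mu, oneshot$mu, tolerance = 1e-8)
  }
  # zero-row update is the identity
  expect_identical(update_posterior(oneshot, matrix(0, 0, 10), numeric(0)),
                   oneshot)
})

test_that("adding data never inflates posterior variance (Loewner order)", {
  set.seed(11)
  post <- fit_posterior(NULL, sigma = 0.7, b = 0.5, p = 8)
  for (step in 1:5) {
    Gb <- posterior_covariance(post)
    post <- update_posterior(post, matrix(rnorm(3 * 8), 3, 8), rnorm(3))
    Ga <- posterior_covariance(post)
    probes <- matrix(rnorm(100 * 8), 100, 8)
    before <- rowSums((probes %*% Gb) * probes)
    after <- rowSums((probes %*% Ga) * probes)
    expect_true(all(after <= before + 1e-10))
    ev <- eigen(Ga, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("posterior recovers dense truth once n exceeds p", {
  # p=20, d=5, sigma=0.01, b=1e-3, 20 experiments of iid N(0,1) rows
  failures <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    beta <- rnorm(20)
    post <- fit_posterior(NULL, sigma = 0.01, b = 1e-3, p = 20)
    for (e in 1:20) {
      X <- matrix(rnorm(5 * 20), 5, 20)
      y <- as.vector(X %*% beta) + 0.01 * rnorm(5)
      post <- update_posterior(post, X, y)
    }
    if (max(abs(post$mu - beta)) >= 0.01) failures <- failures + 1L
  }
  expect_lte(failures, 2L)  # >= 95% of 50 seeds within 0.01 sup-norm
})

test_that("invalid inputs are rejected", {
  expect_error(fit_posterior(list(X = matrix(NA_real_, 1, 2), y = 1), 1, 1),
               "non-finite")
  expect_error(fit_posterior(list(X = matrix(1, 1, 2), y = NaN), 1, 1),
               "non-finite")
  expect_error(fit_posterior(NULL, sigma = 0, b = 1, p = 2), "sigma")
  expect_error(fit_posterior(NULL, sigma = 1, b = -1, p = 2), "b")
  expect_error(fit_posterior(NULL, sigma = 1, b = 1), "p")
  p2 <- fit_posterior(NULL, 1, 1, p = 2)
  expect_error(update_posterior(p2, matrix(1, 1, 3), 1), "columns")
  expect_error(update_posterior(p2, matrix(1, 2, 2), 1), "rows")
})

test_that("z-values, normal p-values and BH decisions follow the ensemble", {
  # no data: mu = 0, all p-values 1, nothing significant
  sig0 <- significance_test(fit_posterior(NULL, 1, 1, p = 4), 0.05)
  expect_equal(sig0$z, rep(0, 4))
  expect_equal(sig0$pval, rep(1, 4))
  expect_false(any(sig0$significant))

  # X = I2, sigma=1, b=1: Gamma = I/2, z = y / sqrt(2)
  y <- c(3.2905 * sqrt(2), 0)
  post <- fit_posterior(list(X = diag(2), y = y), sigma = 1, b = 1)
  sig <- significance_test(post, alpha = 0.01)
  expect_equal(sig$z, c(3.2905, 0), tolerance = 1e-10)
  expect_equal(round(sig$pval, 3), c(0.001, 1))
  expect_equal(sig$significant, c(TRUE, FALSE))
  expect_equal(attr(sig, "alpha"), 0.01)

  # p-values are monotone decreasing in |z|
  ord <- order(abs(sig$z))
  expect_true(all(diff(sig$pval[ord]) <= 0))
})

test_that("BH step-up matches hand evaluation and the brute-force oracle", {
  expect_equal(bh_stepup(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_stepup(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_equal(bh_stepup(c(0.001, 0.02, 0.9), 0.05), c(TRUE, TRUE, FALSE))
  expect_equal(bh_stepup(c(0.01, 0.011, 0.9, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_stepup(numeric(0), 0.05), logical(0))

  set.seed(5)
  for (i in 1:25) {
    m <- sample(1:10, 1)
    pv <- round(runif(m), 2)
    alpha <- runif(1, 0.01, 0.2)
    got <- bh_stepup(pv, alpha)
    expect_identical(got, bh_oracle(pv, alpha))
    # step-up set property: rejections are the smallest p-values
    if (any(got)) expect_true(max(pv[got]) <= min(c(pv[!got], Inf)))
    # monotone in alpha
    expect_true(all(bh_stepup(pv, min(alpha * 2, 0.99)) | !got))
  }
})

test_that("tidy and glance summarize the posterior", {
  post <- fit_posterior(list(X = diag(2), y = c(1, 2)), sigma = 1, b = 1)
  td <- generics::tidy(post)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("index", "mu", "sd"))
  expect_equal(td$sd, rep(sqrt(1 / 2), 2))
  gl <- generics::glance(post)
  expect_equal(gl$p, 2)
  expect_equal(gl$n_obs, 2L)
  expect_equal(gl$n_unexplored, 2)  # both directions equally explored
})
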