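# Maximum-likelihood fitters and the likelihood-ratio test.

test_that("ordinal MLE recovers generating parameters within 3 SEs", {
  set.seed(20)
  n <- 20000
  X <- cbind(rnorm(n))
  m <- ordinal_trait(X, beta = 0.5, theta = c(-1, 0, 1))
  y <- simulate(m, seed = 21)[, 1]
  fit <- fit_ordinal(y, X)
  expect_true(fit$converged)
  est <- c(fit$theta_hat, fit$beta_hat)
  truth <- c(-1, 0, 1, 0.5)
  expect_true(all(abs(est - truth) < 3 * fit$se))
  # loglik at the MLE dominates the truth
  probs_truth <- ordinal_category_probs(m)
  ll_truth <- sum(log(probs_truth[cbind(seq_len(n), y)]))
  expect_gte(fit$loglik, ll_truth)
})

test_that("intercept-only ordinal fit reproduces empirical cumulative freqs", {
  set.seed(22)
  y <- sample(1:4, 500, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  fit <- fit_ordinal(y)
  emp_cum <- cumsum(tabulate(y, 4))[1:3] / 500
  expect_equal(plogis(fit$theta_hat), emp_cum, tolerance = 1e-7)
})

test_that("ordinal fitter agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(23)
  n <- 1500
  X <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  g <- rbinom(n, 2, 0.3)
  m <- ordinal_trait(X, beta = c(0.3, -0.2), theta = c(-1, 0.2, 1.3),
    G = g, gamma = 0.25
  )
  y <- simulate(m, seed = 24)[, 1]
  fit <- fit_ordinal(y, cbind(X, snp = g))
  ref <- MASS::polr(factor(y) ~ X[, 1] + X[, 2] + g, method = "logistic")
  expect_equal(fit$theta_hat, unname(ref$zeta), tolerance = 1e-4)
  expect_equal(unname(fit$beta_hat), unname(coef(ref)), tolerance = 1e-4)
  expect_gte(fit$loglik, as.numeric(logLik(ref)) - 1e-6)
})

test_that("probit and cloglog ordinal links fit their own data", {
  set.seed(25)
  n <- 4000
  X <- cbind(rnorm(n))
  for (link in c("probit", "cloglog")) {
    m <- ordinal_trait(X, beta = 0.4, theta = c(-0.8, 0.6), link = link)
    y <- simulate(m, seed = 26)[, 1]
    fit <- fit_ordinal(y, X, link = link)
    expect_true(fit$converged)
    expect_true(all(abs(c(fit$theta_hat, fit$beta_hat) - c(-0.8, 0.6, 0.4)) <
      4 * fit$se))
  }
})

test_that("ordinal input validation catches unusable responses", {
  expect_error(fit_ordinal(c(1, 1, 3, 3)), "every category")
  expect_error(fit_ordinal(c(1, 1, 1, 1)), "at least 2")
  expect_error(fit_ordinal(c(0, 1, 2)), "1..J")
})

test_that("vcm fit with identity relatedness collapses to linear regression", {
  set.seed(27)
  n <- 100
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, 0.5, -0.2)) + rnorm(n, sd = 0.8)
  fit <- fit_vcm_univariate(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$beta_hat), unname(ols$coefficients), tolerance = 1e-8)
  ml_var <- sum(ols$residuals^2) / n
  expect_equal(fit$sigma_a_hat + fit$sigma_e_hat, ml_var, tolerance = 1e-8)
})

test_that("rotated vcm loglik equals the dense multivariate-normal oracle", {
  set.seed(28)
  n_fam <- 12
  m <- sibship_vcm_model(n_fam, sibs = 4, sigma_a = 0.5, sigma_e = 0.5)
  n <- n_fam * 4
  phi <- sibship_kinship(n_fam, 4, scale = "relationship")
  y <- drop(simulate(m, seed = 29))
  X <- cbind(1, rnorm(n))
  fit <- fit_vcm_univariate(y, X, phi)
  Sigma <- fit$sigma_a_hat * unclass(phi)[, ] + fit$sigma_e_hat * diag(n)
  expect_equal(
    fit$loglik,
    dense_mvn_loglik(y, drop(X %*% fit$beta_hat), Sigma),
    tolerance = 1e-8
  )
})

test_that("vcm variance components are recovered on sibship data", {
  n_fam <- 200
  m <- sibship_vcm_model(n_fam, sibs = 4, sigma_a = 0.4, sigma_e = 0.6)
  phi <- sibship_kinship(n_fam, 4, scale = "relationship")
  rot <- vcm_rotation(phi)
  n <- n_fam * 4
  reps <- 60
  y_all <- simulate(m, nsim = reps, seed = 30)
  est <- t(vapply(seq_len(reps), function(r) {
    f <- fit_vcm_univariate(y_all[, 1, r], matrix(1, n, 1), rotation = rot)
    c(f$sigma_a_hat, f$sigma_e_hat)
  }, c(0, 0)))
  expect_lt(abs(mean(est[, 1]) - 0.4), 0.04)
  expect_lt(abs(mean(est[, 2]) - 0.6), 0.04)
})

test_that("estimator bias shrinks with sample size", {
  sizes <- c(25, 100, 400) # families of 4 sibs -> n = 100, 400, 1600
  bias <- vapply(seq_along(sizes), function(i) {
    n_fam <- sizes[i]
    m <- sibship_vcm_model(n_fam, sibs = 4, sigma_a = 0.4, sigma_e = 0.6,
      seed = 100 + i
    )
    phi <- sibship_kinship(n_fam, 4, scale = "relationship")
    rot <- vcm_rotation(phi)
    reps <- 40
    y_all <- simulate(m, nsim = reps, seed = 31)
    ests <- vapply(seq_len(reps), function(r) {
      fit_vcm_univariate(y_all[, 1, r], matrix(1, n_fam * 4, 1),
        rotation = rot
      )$sigma_a_hat
    }, 0)
    abs(mean(ests) - 0.4)
  }, 0)
  expect_lt(bias[3], bias[1] + 0.02) # monotone up to MC noise
  expect_lt(bias[3], 0.05)
})

test_that("adding the causal SNP never decreases the maximized loglik", {
  set.seed(32)
  n_fam <- 50
  m <- sibship_vcm_model(n_fam, sibs = 4, gamma = 0.3)
  phi <- sibship_kinship(n_fam, 4, scale = "relationship")
  rot <- vcm_rotation(phi)
  n <- n_fam * 4
  for (r in 1:5) {
    y <- drop(simulate(m, seed = 32 + r))
    f0 <- fit_vcm_univariate(y, matrix(1, n, 1), rotation = rot)
    f1 <- fit_vcm_univariate(y, cbind(1, drop(m$G)), rotation = rot)
    expect_gte(f1$loglik, f0$loglik - 1e-8)
  }
})

test_that("vcm null LRT p-values are approximately uniform", {
  n_fam <- 150
  m <- sibship_vcm_model(n_fam, sibs = 4, gamma = 0)
  phi <- sibship_kinship(n_fam, 4, scale = "relationship")
  rot <- vcm_rotation(phi)
  n <- n_fam * 4
  reps <- 1000
  y_all <- simulate(m, nsim = reps, seed = 33)
  pv <- vapply(seq_len(reps), function(r) {
    y <- y_all[, 1, r]
    f0 <- fit_vcm_univariate(y, matrix(1, n, 1), rotation = rot)
    f1 <- fit_vcm_univariate(y, cbind(1, drop(m$G)), rotation = rot)
    lrt_pvalue(f0$loglik, f1$loglik, 1)
  }, 0)
  ks <- max(abs(sort(pv) - seq_len(reps) / reps))
  expect_lt(ks, 1.628 / sqrt(reps)) # 1% critical value
})

test_that("degenerate and boundary inputs are handled", {
  set.seed(34)
  n <- 60
  X <- cbind(1, rnorm(n))
  # pure noise: sigma_a should hit the zero boundary often; never negative
  y <- rnorm(n)
  f <- fit_vcm_univariate(y, X, sibship_kinship(15, 4, scale = "relationship"))
  expect_gte(f$sigma_a_hat, 0)
  expect_gte(f$sigma_e_hat, 0)
  expect_error(fit_vcm_univariate(y, cbind(X, X[, 1]), diag(n)), "full column rank")
})

test_that("the LRT maps statistics to calibrated p-values", {
  expect_equal(lrt_pvalue(-10, -10, 1), 1)
  expect_equal(lrt_pvalue(0, 3.841459 / 2, 1), 0.05, tolerance = 1e-6)
  expect_equal(lrt_pvalue(0, 29.7168 / 2, 1), 5e-8, tolerance = 1e-3)
  expect_equal(lrt_pvalue(0, -1e-9, 1), 1) # numerical slack clipped
  expect_error(lrt_pvalue(0, 1, 0), "df")
  expect_error(lrt_pvalue(0, -1, 1), "not nested")
})
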