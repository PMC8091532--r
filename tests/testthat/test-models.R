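# Trait-model constructors and the polymorphic simulate() entry point.

test_that("normal/identity with zero residual sd is exactly X beta + G gamma", {
  set.seed(1)
  X <- cbind(1, rnorm(30))
  G <- cbind(rbinom(30, 2, 0.3))
  m <- glm_trait(X, c(0.5, 1), G = G, gamma = 0.7, dist = "normal", sd = 0)
  y <- simulate(m, seed = 2)
  expect_equal(y[, 1], drop(X %*% c(0.5, 1) + G * 0.7))
})

test_that("identical (model, seed) pairs give bit-identical draws", {
  set.seed(2)
  X <- cbind(1, rnorm(40))
  models <- list(
    glm_trait(X, c(0, 1), dist = "poisson", link = "log"),
    ordinal_trait(X[, 2, drop = FALSE], 0.5, theta = c(-1, 1)),
    vcm_trait(X, B = c(0, 0),
      components = list(variance_component(1, diag(40)))
    ),
    glmm_trait(X, c(0, 0.2),
      components = list(variance_component(0.3, diag(40))),
      dist = "bernoulli", link = "logit"
    )
  )
  for (m in models) {
    expect_identical(simulate(m, nsim = 3, seed = 99), simulate(m, nsim = 3, seed = 99))
  }
})

test_that("poisson/log empirical mean matches exp(eta) within a CLT band", {
  n <- 50000
  m <- glm_trait(matrix(1, n, 1), beta = 1, dist = "poisson", link = "log")
  y <- simulate(m, seed = 5)
  expect_lt(abs(mean(y) - exp(1)), 3 * sqrt(exp(1) / n))
})

test_that("unlisted family/link pairings are rejected up front", {
  X <- matrix(1, 5, 1)
  expect_error(glm_trait(X, 1, dist = "poisson", link = "identity"), "not supported")
  expect_error(glm_trait(X, 1, dist = "bernoulli", link = "log"), "not supported")
  expect_error(glm_trait(X, 1, dist = "negative_binomial", link = "logit"), "not supported")
  expect_error(glm_trait(X, 1, dist = "binomial", link = "logit"), "trials")
  expect_error(ordinal_trait(X, 1, theta = c(1, 0)), "nondecreasing")
})

test_that("family draws honour their nuisance parameters", {
  n <- 40000
  X <- matrix(1, n, 1)
  yb <- simulate(glm_trait(X, 0, dist = "binomial", link = "logit", trials = 7),
    seed = 1
  )
  expect_true(all(yb >= 0 & yb <= 7))
  expect_lt(abs(mean(yb) - 3.5), 4 * sqrt(7 * 0.25 / n))
  ynb <- simulate(
    glm_trait(X, log(4), dist = "negative_binomial", link = "log", dispersion = 2),
    seed = 2
  )
  # variance mu + mu^2 / r = 4 + 8 = 12
  expect_lt(abs(mean(ynb) - 4), 4 * sqrt(12 / n))
  expect_lt(abs(var(ynb[, 1]) - 12), 0.8)
  yg <- simulate(glm_trait(X, log(2), dist = "gamma", link = "log", shape = 3),
    seed = 3
  )
  expect_lt(abs(mean(yg) - 2), 4 * sqrt(4 / 3 / n))
})

test_that("ordinal category probabilities match the closed-form example", {
  m <- ordinal_trait(matrix(0, 1, 0), numeric(0), theta = c(0, 1, 2))
  pr <- ordinal_category_probs(m)
  expect_equal(
    unname(pr[1, ]),
    c(0.5, 0.231059, 0.149738, 0.119203),
    tolerance = 1e-5
  )
  expect_equal(rowSums(pr), 1)
  m2 <- ordinal_trait(matrix(0, 1, 0), numeric(0), theta = 0)
  expect_equal(unname(ordinal_category_probs(m2)[1, ]), c(0.5, 0.5))
})

test_that("category probabilities telescope for any theta and eta", {
  set.seed(3)
  for (link in c("logit", "probit", "cloglog")) {
    m <- ordinal_trait(matrix(rnorm(20), 20, 1), 0.8,
      theta = sort(rnorm(4)), link = link
    )
    pr <- ordinal_category_probs(m)
    expect_true(all(pr >= 0))
    expect_equal(rowSums(pr), rep(1, 20))
  }
})

test_that("saturated intercepts force the middle category", {
  m <- ordinal_trait(matrix(0, 50, 0), numeric(0), theta = c(-50, 50))
  y <- simulate(m, seed = 1)
  expect_true(all(y == 2L))
})

test_that("dichotomization equals cutting the same ordinal draw stream", {
  set.seed(4)
  m <- ordinal_trait(matrix(rnorm(500), 500, 1), 0.5, theta = c(0, 1, 2))
  y_ord <- simulate(m, nsim = 3, seed = 77)
  y_bin <- simulate(m, nsim = 3, seed = 77, logistic = TRUE, cutoff = 2)
  expect_identical(y_bin, (y_ord > 2) * 1L)
  # mean matches 1 - F(theta_2 - eta) at eta = 0
  m0 <- ordinal_trait(matrix(0, 100000, 0), numeric(0), theta = c(0, 1, 2))
  yb <- simulate(m0, seed = 5, logistic = TRUE, cutoff = 2)
  expect_lt(abs(mean(yb) - 0.268941), 3 * sqrt(0.269 * 0.731 / 100000))
  expect_error(simulate(m, logistic = TRUE, cutoff = 5), "cutoff")
  expect_error(simulate(m, logistic = TRUE), "cutoff")
})

test_that("matrix-normal draws have the advertised moments", {
  # null component: exact zeros
  z <- sample_matrix_normal(matrix(0, 2, 2), diag(3), seed = 1)
  expect_equal(z, matrix(0, 3, 2))
  # d = 1, V = I: iid N(0, sigma2)
  draws <- sample_matrix_normal(2.5, diag(1), nsim = 100000, seed = 2)
  v <- var(as.vector(draws))
  expect_lt(abs(v - 2.5), 3 * 2.5 * sqrt(2 / 100000))
  expect_error(
    sample_matrix_normal(matrix(c(1, 2, 2, 1), 2, 2), diag(2)),
    "positive semidefinite"
  )
})

test_that("vcm with zero genetic component collapses to white noise", {
  n <- 2000
  phi <- sibship_kinship(n / 2, 2, scale = "relationship")
  m <- vcm_trait(matrix(1, n, 1), B = 0,
    components = list(
      variance_component(0, phi),
      variance_component(1, diag(n))
    )
  )
  y <- simulate(m, nsim = 20, seed = 6)
  expect_lt(abs(mean(y)), 3 / sqrt(20 * n))
  expect_lt(abs(var(as.vector(y)) - 1), 3 * sqrt(2 / (20 * n)))
})

test_that("sibship vcm reproduces the within-family covariance 0.5 sigma_a", {
  n_fam <- 250
  m <- sibship_vcm_model(n_fam, sibs = 2, sigma_a = 0.6, sigma_e = 0.4)
  reps <- 200
  y <- simulate(m, nsim = reps, seed = 7) # n x 1 x reps
  s1 <- matrix(y[seq(1, 2 * n_fam, 2), 1, ], ncol = reps)
  s2 <- matrix(y[seq(2, 2 * n_fam, 2), 1, ], ncol = reps)
  cv <- mean(colMeans(s1 * s2)) # mean zero construction
  mc_se <- sd(colMeans(s1 * s2)) / sqrt(reps)
  expect_lt(abs(cv - 0.5 * 0.6), 4 * mc_se)
})

test_that("glmm with null variance components matches the pure GLM moments", {
  n <- 2000
  nsim <- 50
  X <- matrix(1, n, 1)
  mg <- glmm_trait(X, 0.3,
    components = list(variance_component(0, diag(n))),
    dist = "poisson", link = "log"
  )
  y_mm <- as.vector(simulate(mg, nsim = nsim, seed = 8))
  y_glm <- as.vector(
    simulate(glm_trait(X, 0.3, dist = "poisson", link = "log"), nsim = nsim, seed = 9)
  )
  se_mean <- sqrt(2 * exp(0.3) / (n * nsim))
  expect_lt(abs(mean(y_mm) - mean(y_glm)), 4 * se_mean)
  expect_lt(abs(var(y_mm) - var(y_glm)), 12 * se_mean)
})

test_that("glmm poisson marginal mean is the lognormal-rate mean", {
  n <- 2000
  nsim <- 100
  mg <- glmm_trait(matrix(1, n, 1), 0,
    components = list(variance_component(0.25, diag(n))),
    dist = "poisson", link = "log"
  )
  y <- simulate(mg, nsim = nsim, seed = 10)
  target <- exp(0.25 / 2)
  # var(y) = E[lambda] + var(lambda); var(lambda) = e^{s2}(e^{s2}-1)
  vy <- target + exp(0.25) * (exp(0.25) - 1)
  expect_lt(abs(mean(y) - target), 4 * sqrt(vy / (n * nsim)))
})

test_that("glmm random intercepts create overdispersion", {
  # binomial counts with a per-observation latent intercept: by the law
  # of total variance, var(y) exceeds the binomial variance at the
  # marginal mean by (trials^2 - trials) * var of the success probability
  n <- 2000
  mg <- glmm_trait(matrix(0, n, 0), numeric(0),
    components = list(variance_component(1, diag(n))),
    dist = "binomial", link = "logit", trials = 10
  )
  y <- as.vector(simulate(mg, nsim = 10, seed = 11))
  p_marg <- mean(y) / 10
  v_binom <- 10 * p_marg * (1 - p_marg)
  expect_gt(var(y), 1.5 * v_binom)

  # shared bernoulli intercepts within blocks inflate block-mean variance
  n_blocks <- 200
  k <- 5
  V <- kronecker(diag(n_blocks), matrix(1, k, k))
  mb <- glmm_trait(matrix(0, n_blocks * k, 0), numeric(0),
    components = list(variance_component(1.5, V)),
    dist = "bernoulli", link = "logit"
  )
  yb <- matrix(simulate(mb, nsim = 50, seed = 12), nrow = k)
  bm <- colMeans(yb)
  pm <- mean(yb)
  expect_gt(var(bm), 1.5 * pm * (1 - pm) / k)
})
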