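# Maximum-likelihood analysis engines for the power loop: proportional-odds
# ordinal regression (Newton with step-halving on a monotone
# reparameterization) and the univariate variance-component model (one-time
# eigenrotation, fixed effects and total variance profiled out, 1-D
# heritability search), plus the likelihood-ratio test.

# ---- ordinal proportional-odds fitter -------------------------------------

# log-likelihood and analytic gradient in the natural (theta, beta) scale
ordinal_loglik_grad <- function(theta, beta, y, X, fns) {
  n <- length(y)
  eta <- if (ncol(X)) drop(X %*% beta) else rep(0, n)
  thL <- c(-Inf, theta)[y] # theta_{y-1}
  thU <- c(theta, Inf)[y] # theta_{y}
  a <- thU - eta
  b <- thL - eta
  Fa <- ifelse(is.finite(a), fns$cdf(a), 1)
  Fb <- ifelse(is.finite(b), fns$cdf(b), 0)
  fa <- ifelse(is.finite(a), fns$pdf(a), 0)
  fb <- ifelse(is.finite(b), fns$pdf(b), 0)
  pi_i <- pmax(Fa - Fb, 1e-300)
  ll <- sum(log(pi_i))
  J1 <- length(theta)
  gtheta <- numeric(J1)
  wa <- fa / pi_i
  wb <- fb / pi_i
  for (j in seq_len(J1)) {
    gtheta[j] <- sum(wa[y == j]) - sum(wb[y == j + 1L])
  }
  gbeta <- if (ncol(X)) drop(crossprod(X, -(wa - wb))) else numeric(0)
  list(ll = ll, grad = c(gtheta, gbeta))
}

# zeta = (theta_1, log gaps, beta) <-> (theta, beta); gaps keep theta ordered
zeta_to_theta <- function(zeta, J1) {
  if (J1 == 1) {
    zeta[1]
  } else {
    cumsum(c(zeta[1], exp(zeta[2:J1])))
  }
}

zeta_grad <- function(grad_theta_beta, zeta, J1) {
  gt <- grad_theta_beta[seq_len(J1)]
  gb <- grad_theta_beta[-seq_len(J1)]
  gz <- numeric(J1)
  gz[1] <- sum(gt)
  if (J1 > 1) {
    for (m in 2:J1) {
      gz[m] <- exp(zeta[m]) * sum(gt[m:J1])
    }
  }
  c(gz, gb)
}

#' Fit a proportional-odds ordinal regression by maximum likelihood
#'
#' Maximizes the multinomial log-likelihood of the cumulative link model
#' \eqn{g(\Pr(y_i \le j)) = \theta_j - X_i'\beta} by Newton iterations
#' with step-halving on the reparameterized scale \eqn{(\theta_1,
#' \log(\theta_2-\theta_1), \dots, \beta)}, which keeps the category
#' intercepts strictly ordered. The Hessian is a central finite
#' difference of the analytic gradient. Convergence is declared when the
#' gradient max-norm falls below \code{tol}.
#'
#' @param y Integer response with categories 1..J; every category must be
#'   observed at least once.
#' @param X n x p design matrix of covariates, \emph{without} an intercept
#'   column (the intercepts are the \eqn{\theta_j}); \code{NULL} for an
#'   intercept-only fit.
#' @param link \code{"logit"} (default), \code{"probit"} or
#'   \code{"cloglog"}.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Gradient max-norm convergence tolerance (default 1e-8).
#' @param compute_se If \code{TRUE} (default), invert the observed
#'   information at the MLE for standard errors; skip inside tight
#'   replicate loops where only the log-likelihood is needed.
#' @return An object of class \code{ordinal_fit}: \code{theta_hat},
#'   \code{beta_hat}, \code{loglik}, \code{converged}, \code{n_iter},
#'   \code{vcov} (inverse observed information for \eqn{(\theta,\beta)}),
#'   \code{se} (its square-root diagonal).
#' @export
#' @examples
#' m <- ordinal_trait(matrix(rnorm(200), 200, 1), beta = 0.5, theta = c(-1, 0, 1))
#' y <- simulate(m, seed = 1)[, 1]
#' fit_ordinal(y, m$X)
fit_ordinal <- function(y, X = NULL, link = "logit",
                        max_iter = 100L, tol = 1e-8, compute_se = TRUE) {
  y <- as.integer(y)
  J <- max(y)
  if (min(y) < 1) stop("y must contain categories 1..J", call. = FALSE)
  if (!all(seq_len(J) %in% y)) {
    stop("every category 1..J must be observed at least once", call. = FALSE)
  }
  if (J < 2) stop("y must have at least 2 observed categories", call. = FALSE)
  n <- length(y)
  X <- as_design(X, n = n)
  if (nrow(X) != n) stop("X must have length(y) rows", call. = FALSE)
  p <- ncol(X)
  fns <- ordinal_link_funs(link)
  J1 <- J - 1L
  # start: intercepts from empirical cumulative frequencies, beta = 0
  cumfreq <- cumsum(tabulate(y, J))[seq_len(J1)] / n
  qfun <- switch(link,
    logit = stats::qlogis,
    probit = stats::qnorm,
    cloglog = function(q) log(-log1p(-q))
  )
  theta0 <- qfun(pmin(pmax(cumfreq, 1e-6), 1 - 1e-6))
  theta0 <- theta0 + cumsum(c(0, rep(1e-8, J1 - 1))) # break exact ties
  zeta <- c(theta0[1], if (J1 > 1) log(pmax(diff(theta0), 1e-6)), rep(0, p))
  npar <- J1 + p
  eval_zeta <- function(z) {
    th <- zeta_to_theta(z, J1)
    be <- if (p) z[(J1 + 1):npar] else numeric(0)
    r <- ordinal_loglik_grad(th, be, y, X, fns)
    list(ll = r$ll, grad = zeta_grad(r$grad, z, J1))
  }
  cur <- eval_zeta(zeta)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    if (max(abs(cur$grad)) < tol) {
      converged <- TRUE
      break
    }
    # central-difference Hessian of the gradient
    H <- matrix(0, npar, npar)
    h <- 1e-6 * pmax(1, abs(zeta))
    for (m in seq_len(npar)) {
      zp <- zeta
      zp[m] <- zp[m] + h[m]
      zm <- zeta
      zm[m] <- zm[m] - h[m]
      H[, m] <- (eval_zeta(zp)$grad - eval_zeta(zm)$grad) / (2 * h[m])
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(-solve(H, cur$grad), error = function(e) NULL)
    ridge <- max(abs(diag(H)), 1) * 1e-6
    while (is.null(step) || !all(is.finite(step))) {
      step <- tryCatch(-solve(H - ridge * diag(npar), cur$grad),
        error = function(e) NULL
      )
      ridge <- ridge * 10
      if (ridge > 1e12) break
    }
    if (is.null(step) || !all(is.finite(step))) {
      step <- cur$grad / max(1, max(abs(cur$grad))) # gradient fallback
    }
    # step-halving
    lam <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- zeta + lam * step
      new <- eval_zeta(cand)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) {
        zeta <- cand
        cur <- new
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (max(abs(cur$grad)) < tol) converged <- TRUE
  theta_hat <- zeta_to_theta(zeta, J1)
  beta_hat <- if (p) zeta[(J1 + 1):npar] else numeric(0)
  # observed information in the natural (theta, beta) scale for SEs
  vcov <- se <- NULL
  if (compute_se) {
    nat <- c(theta_hat, beta_hat)
    Hnat <- matrix(0, npar, npar)
    h <- 1e-6 * pmax(1, abs(nat))
    gfun <- function(v) {
      ordinal_loglik_grad(
        v[seq_len(J1)], if (p) v[(J1 + 1):npar] else numeric(0), y, X, fns
      )$grad
    }
    for (m in seq_len(npar)) {
      vp <- nat
      vp[m] <- vp[m] + h[m]
      vm <- nat
      vm[m] <- vm[m] - h[m]
      Hnat[, m] <- (gfun(vp) - gfun(vm)) / (2 * h[m])
    }
    Hnat <- (Hnat + t(Hnat)) / 2
    vcov <- tryCatch(solve(-Hnat), error = function(e) NULL)
    if (!is.null(vcov)) {
      se <- sqrt(pmax(diag(vcov), 0))
    }
  }
  if (p && !is.null(colnames(X))) {
    names(beta_hat) <- colnames(X)
  }
  structure(
    list(
      theta_hat = theta_hat, beta_hat = beta_hat,
      loglik = cur$ll, converged = converged, n_iter = n_iter,
      J = J, link = link, vcov = vcov, se = se, n = n
    ),
    class = "ordinal_fit"
  )
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(
    "ordinal_fit (", x$link, "): J =", x$J, ", n =", x$n,
    ", loglik =", format(x$loglik), ",",
    if (x$converged) "converged" else "NOT converged",
    "in", x$n_iter, "iterations\n"
  )
  cat("theta:", format(x$theta_hat, digits = 4), "\n")
  if (length(x$beta_hat)) cat("beta: ", format(x$beta_hat, digits = 4), "\n")
  invisible(x)
}

# ---- univariate variance-component fitter ---------------------------------

#' Precompute the eigenrotation of a relatedness matrix
#'
#' The univariate variance-component fitter diagonalizes the relatedness
#' matrix once: with \eqn{\Phi = U D U'}, rotating the data by \eqn{U'}
#' makes the trait covariance diagonal, \eqn{\sigma_A d_i + \sigma_E}.
#' Precompute this when fitting many replicates against the same
#' \eqn{\Phi} (the dominant cost for large n).
#'
#' @param Phi n x n symmetric PSD relatedness matrix (kinship, GRM, or a
#'   \code{grm} object).
#' @return An object of class \code{vcm_rotation} with elements \code{U}
#'   (eigenvectors) and \code{d} (nonnegative eigenvalues).
#' @export
vcm_rotation <- function(Phi) {
  if (inherits(Phi, "grm")) Phi <- Phi$matrix
  Phi <- as.matrix(Phi)
  if (max(abs(Phi - t(Phi))) > 1e-8 * max(1, max(abs(Phi)))) {
    stop("Phi must be symmetric", call. = FALSE)
  }
  e <- eigen(Phi, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(1, max(abs(e$values)))) {
    stop("Phi is not positive semidefinite", call. = FALSE)
  }
  structure(list(U = e$vectors, d = pmax(e$values, 0)), class = "vcm_rotation")
}

#' Fit the univariate two-component mixed model by maximum likelihood
#'
#' Fits \eqn{y \sim N(X\beta, \sigma_A \Phi + \sigma_E I)} by full maximum
#' likelihood (not REML, so that likelihood-ratio tests of nested fixed
#' effects are coherent). After the one-time eigenrotation of \eqn{\Phi}
#' the covariance is diagonal; \eqn{\beta} is profiled out by weighted
#' least squares and the total variance \eqn{\sigma^2 = \sigma_A +
#' \sigma_E} analytically, leaving a 1-D search over the heritability
#' ratio \eqn{h = \sigma_A / \sigma^2 \in [0, 1]} (grid scan plus local
#' refinement), which handles the \eqn{\sigma_A = 0} boundary exactly.
#'
#' @param y Numeric response vector.
#' @param X n x p design matrix of fixed effects, full column rank
#'   (include an intercept column).
#' @param Phi n x n symmetric PSD relatedness matrix, a \code{grm}
#'   object, or \code{NULL} when \code{rotation} is supplied.
#' @param rotation Optional precomputed [vcm_rotation()] of \code{Phi}.
#' @return An object of class \code{vcm_fit}: \code{sigma_a_hat},
#'   \code{sigma_e_hat}, \code{beta_hat}, \code{h2_hat}, \code{loglik},
#'   \code{converged}.
#' @export
#' @examples
#' phi <- sibship_kinship(50, 4, scale = "relationship")
#' m <- vcm_trait(matrix(1, 200, 1), B = 0,
#'   components = list(variance_component(0.4, phi), variance_component(0.6, diag(200))))
#' y <- simulate(m, seed = 1)[, 1, 1]
#' fit_vcm_univariate(y, matrix(1, 200, 1), phi)
fit_vcm_univariate <- function(y, X, Phi = NULL, rotation = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as_design(X, n = n)
  if (nrow(X) != n) stop("X must have length(y) rows", call. = FALSE)
  p <- ncol(X)
  if (p < 1 || qr(X)$rank < p) {
    stop("X must have full column rank (include an intercept)", call. = FALSE)
  }
  if (is.null(rotation)) {
    if (is.null(Phi)) stop("either Phi or rotation must be given", call. = FALSE)
    rotation <- vcm_rotation(Phi)
  }
  stopifnot(inherits(rotation, "vcm_rotation"))
  if (length(rotation$d) != n) {
    stop("rotation dimension does not match length(y)", call. = FALSE)
  }
  d <- rotation$d
  yt <- drop(crossprod(rotation$U, y))
  Xt <- crossprod(rotation$U, X)
  # profile log-likelihood of the heritability ratio h
  profile <- function(h) {
    v0 <- h * d + (1 - h)
    v0 <- pmax(v0, 1e-10)
    w <- 1 / v0
    A <- crossprod(Xt, Xt * w)
    b <- crossprod(Xt, yt * w)
    beta <- solve(A, b)
    r <- yt - drop(Xt %*% beta)
    s2 <- sum(w * r^2) / n
    s2 <- max(s2, 1e-12)
    ll <- -0.5 * (sum(log(v0)) + n * log(s2) + n + n * log(2 * pi))
    list(ll = ll, beta = drop(beta), s2 = s2)
  }
  grid <- seq(0, 1, by = 0.02)
  lls <- vapply(grid, function(h) profile(h)$ll, 0)
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(h) profile(h)$ll,
    interval = c(lo, hi), maximum = TRUE, tol = 1e-10
  )
  h_hat <- opt$maximum
  # snap to the boundary when it is at least as good
  for (hb in c(0, 1)) {
    if (profile(hb)$ll >= opt$objective - 1e-10) h_hat <- hb
  }
  fit <- profile(h_hat)
  beta_hat <- fit$beta
  names(beta_hat) <- colnames(X)
  structure(
    list(
      sigma_a_hat = fit$s2 * h_hat,
      sigma_e_hat = fit$s2 * (1 - h_hat),
      h2_hat = h_hat,
      beta_hat = beta_hat,
      loglik = fit$ll,
      converged = TRUE,
      n = n
    ),
    class = "vcm_fit"
  )
}

#' @export
print.vcm_fit <- function(x, ...) {
  cat(
    "vcm_fit: sigma_a =", format(x$sigma_a_hat, digits = 4),
    ", sigma_e =", format(x$sigma_e_hat, digits = 4),
    ", h2 =", format(x$h2_hat, digits = 3),
    ", loglik =", format(x$loglik), "\n"
  )
  cat("beta:", format(x$beta_hat, digits = 4), "\n")
  invisible(x)
}

# ---- likelihood-ratio test ------------------------------------------------

#' Likelihood-ratio test p-value
#'
#' Upper-tail chi-square probability of \eqn{2(\ell_A - \ell_0)} on
#' \code{df} degrees of freedom. Small negative statistics (numerical
#' slack up to 1e-8) are clipped to zero.
#'
#' @param loglik_null Maximized log-likelihood of the null model.
#' @param loglik_alt Maximized log-likelihood of the alternative
#'   (must not fall below the null beyond numerical slack).
#' @param df Degrees of freedom, at least 1.
#' @return The p-value.
#' @export
#' @examples
#' lrt_pvalue(0, 3.841459 / 2, df = 1) # 0.05
lrt_pvalue <- function(loglik_null, loglik_alt, df) {
  if (!is_number(df) || df < 1) stop("df must be >= 1", call. = FALSE)
  if (!is_number(loglik_null) || !is_number(loglik_alt)) {
    stop("log-likelihoods must be finite numbers", call. = FALSE)
  }
  if (loglik_alt < loglik_null - 1e-8) {
    stop("alternative log-likelihood is below the null: models are not nested or a fit failed",
      call. = FALSE
    )
  }
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}
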