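# Simulation methods: one polymorphic simulate() entry point (the base R
# stats::simulate generic) dispatching on the trait-model class, plus the
# matrix-normal sampler that realizes Kronecker-structured covariance
# without ever forming the n*d x n*d matrix.

set_sim_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

# Draw nsim samples from a family at mean mu (matrix), vectorized.
draw_family <- function(dist, mu, aux) {
  nn <- length(mu)
  out <- switch(dist,
    normal = stats::rnorm(nn, mean = mu, sd = aux$sd),
    bernoulli = stats::rbinom(nn, 1L, check_prob(mu)),
    # the link acts on the success probability; the mean is trials * p
    binomial = stats::rbinom(nn, aux$trials, check_prob(mu)),
    poisson = stats::rpois(nn, check_positive(mu, zero_ok = TRUE)),
    negative_binomial = stats::rnbinom(nn,
      size = aux$dispersion,
      mu = check_positive(mu, zero_ok = TRUE)
    ),
    gamma = stats::rgamma(nn, shape = aux$shape, rate = aux$shape / check_positive(mu)),
    exponential = stats::rexp(nn, rate = 1 / check_positive(mu)),
    stop("unknown family: ", dist, call. = FALSE)
  )
  matrix(out, nrow = nrow(mu), ncol = ncol(mu))
}

check_prob <- function(mu) {
  if (any(mu < 0 | mu > 1)) {
    stop("inverse link produced a probability outside [0, 1]", call. = FALSE)
  }
  mu
}

check_positive <- function(mu, zero_ok = FALSE) {
  if (any(if (zero_ok) mu < 0 else mu <= 0)) {
    stop("inverse link produced a mean outside the family's domain", call. = FALSE)
  }
  mu
}

#' Simulate phenotypes from a trait model
#'
#' One polymorphic entry point: \code{simulate()} dispatches on the model
#' class (\code{glm_trait}, \code{ordinal_trait}, \code{vcm_trait},
#' \code{glmm_trait}) and draws \code{nsim} independent phenotype
#' replicates from the model's generative law. Identical (model, seed)
#' pairs produce identical output.
#'
#' @param object A trait model.
#' @param nsim Number of replicates.
#' @param seed Optional integer passed to \code{set.seed()}.
#' @param ... Method-specific arguments; the ordinal method accepts
#'   \code{logistic} and \code{cutoff} (see
#'   [simulate.ordinal_trait()]).
#' @return \code{glm_trait}, \code{glmm_trait}, \code{ordinal_trait}:
#'   an n x nsim matrix. \code{vcm_trait}: an n x d x nsim array.
#' @name simulate-methods
NULL

#' @rdname simulate-methods
#' @export
simulate.glm_trait <- function(object, nsim = 1, seed = NULL, ...) {
  set_sim_seed(seed)
  eta <- linear_predictor(object$X, object$beta, object$G, object$gamma)
  mu <- linkinv_fun(object$link)(eta)
  mu_mat <- matrix(mu, nrow = object$n, ncol = nsim)
  draw_family(object$dist, mu_mat, object$aux)
}

#' Category probabilities of an ordinal trait model
#'
#' Evaluates \eqn{\pi_{ij} = F(\theta_j - \eta_i) - F(\theta_{j-1} -
#' \eta_i)} with \eqn{F} the link's CDF, \eqn{\theta_0 = -\infty},
#' \eqn{\theta_J = +\infty}; each row sums to 1.
#'
#' @param model An [ordinal_trait()] model.
#' @return n x J matrix of category probabilities.
#' @export
#' @examples
#' m <- ordinal_trait(matrix(0, 1, 0), beta = numeric(0), theta = c(0, 1, 2))
#' ordinal_category_probs(m)
ordinal_category_probs <- function(model) {
  stopifnot(inherits(model, "ordinal_trait"))
  cum <- ordinal_cumulative(model)
  J <- model$J
  probs <- cbind(cum, 1)[, seq_len(J), drop = FALSE] -
    cbind(0, cum)[, seq_len(J), drop = FALSE]
  colnames(probs) <- sprintf("cat%d", seq_len(J))
  probs
}

# n x (J-1) matrix of cumulative probabilities F(theta_j - eta_i)
ordinal_cumulative <- function(model) {
  fns <- ordinal_link_funs(model$link)
  eta <- drop(linear_predictor(model$X, model$beta, model$G, model$gamma))
  if (length(eta) == 0) eta <- rep(0, model$n)
  outer(eta, model$theta, function(e, th) fns$cdf(th - e))
}

#' Simulate an ordinal (or dichotomized case/control) trait
#'
#' Draws each \eqn{y_i} from its category distribution
#' ([ordinal_category_probs()]). With \code{logistic = TRUE} the ordinal
#' draw stream is dichotomized at \code{cutoff}: the binary outcome is the
#' indicator \eqn{[y_i > \mathrm{cutoff}]} (categories above the cutoff
#' form the case group), using the same underlying draws, so the binary
#' trait equals the dichotomized ordinal trait replicate for replicate.
#'
#' @param object An [ordinal_trait()] model.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param logistic If \code{TRUE}, return the binary indicator instead of
#'   the category.
#' @param cutoff Category threshold, required when \code{logistic = TRUE};
#'   must lie in 1..(J-1).
#' @param ... Unused.
#' @return n x nsim integer matrix of categories in 1..J, or of 0/1
#'   indicators when \code{logistic = TRUE}.
#' @export
simulate.ordinal_trait <- function(object, nsim = 1, seed = NULL,
                                   logistic = FALSE, cutoff = NULL, ...) {
  set_sim_seed(seed)
  if (logistic) {
    if (is.null(cutoff) || !is_number(cutoff) ||
      cutoff < 1 || cutoff > object$J - 1) {
      stop("cutoff must lie in 1..J-1 when logistic = TRUE", call. = FALSE)
    }
  }
  cum <- ordinal_cumulative(object)
  n <- object$n
  u <- matrix(stats::runif(n * nsim), nrow = n)
  y <- matrix(1L, nrow = n, ncol = nsim)
  for (j in seq_len(object$J - 1L)) {
    y <- y + (u > cum[, j]) # category = 1 + #{thresholds passed}
  }
  if (logistic) {
    storage.mode(y) <- "integer"
    return((y > cutoff) * 1L)
  }
  y
}

#' Sample from a matrix normal distribution with Kronecker covariance
#'
#' Draws n x d matrices \eqn{E = L_V Z L_\Sigma'} with Z standard normal,
#' so that \eqn{\mathrm{cov}(\mathrm{vec}(E)) = \Sigma \otimes V}. The
#' Kronecker covariance is never assembled; only the PSD square roots of
#' the d x d and n x n factors are used.
#'
#' @param sigma d x d symmetric PSD trait covariance (scalar allowed).
#' @param V n x n symmetric PSD relatedness matrix.
#' @param nsim Number of draws.
#' @param seed Optional integer seed.
#' @return n x d matrix if \code{nsim = 1}, else n x d x nsim array.
#' @export
#' @examples
#' e <- sample_matrix_normal(diag(2), diag(3), seed = 1)
sample_matrix_normal <- function(sigma, V, nsim = 1, seed = NULL) {
  set_sim_seed(seed)
  vc <- variance_component(sigma, V)
  out <- draw_components(list(vc), nsim)
  if (nsim == 1) matrix(out, nrow = vc$n, ncol = vc$d) else out
}

# Sum of matrix-normal draws over components, using cached factors.
# Returns an n x d x nsim array.
draw_components <- function(components, nsim) {
  n <- components[[1]]$n
  d <- components[[1]]$d
  total <- array(0, dim = c(n, d, nsim))
  for (vc in components) {
    if (all(vc$L_sigma == 0)) next # null component contributes exactly zero
    Z <- matrix(stats::rnorm(n * d * nsim), nrow = n)
    W <- vc$L_V %*% Z # n x (d*nsim)
    W <- array(W, dim = c(n, d, nsim))
    Ls <- vc$L_sigma
    # right-multiply each slice by t(L_sigma): loop over the d^2 entries
    for (j in seq_len(d)) {
      acc <- matrix(0, n, nsim)
      for (k in seq_len(d)) {
        if (Ls[j, k] != 0) acc <- acc + Ls[j, k] * matrix(W[, k, ], n, nsim)
      }
      total[, j, ] <- total[, j, ] + acc
    }
  }
  total
}

#' Simulate a (possibly multivariate) variance-component trait
#'
#' Draws \eqn{Y = XB + G\Gamma + \sum_c E_c} with each \eqn{E_c} an
#' independent matrix-normal draw with covariance
#' \eqn{\Sigma^{(c)} \otimes V^{(c)}} (see [sample_matrix_normal()]).
#'
#' @param object A [vcm_trait()] model.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return n x d x nsim array (use \code{drop = TRUE} on the result, or
#'   \code{[ , , 1]}, for a single univariate replicate).
#' @export
simulate.vcm_trait <- function(object, nsim = 1, seed = NULL, ...) {
  set_sim_seed(seed)
  mean_mat <- object$X %*% object$B
  if (!is.null(object$G)) {
    mean_mat <- mean_mat + object$G %*% object$Gamma
  }
  out <- draw_components(object$components, nsim)
  out + as.vector(mean_mat) # recycles the n*d mean over replicates
}

#' Simulate a generalized linear mixed trait
#'
#' Draws the random effect \eqn{u \sim N(0, \sum_c \sigma^{(c)} V^{(c)})}
#' once per replicate, forms \eqn{\eta = X\beta + G\gamma + u}, and draws
#' conditionally independent responses from the family at
#' \eqn{\mu = g^{-1}(\eta)}.
#'
#' @param object A [glmm_trait()] model.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return n x nsim matrix.
#' @export
simulate.glmm_trait <- function(object, nsim = 1, seed = NULL, ...) {
  set_sim_seed(seed)
  eta_fixed <- linear_predictor(object$X, object$beta, object$G, object$gamma)
  u <- draw_components(object$components, nsim) # n x 1 x nsim
  eta <- matrix(u, nrow = object$n, ncol = nsim) + as.vector(eta_fixed)
  mu <- linkinv_fun(object$link)(eta)
  draw_family(object$dist, mu, object$aux)
}
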