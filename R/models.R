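# Trait-model constructors: generalized linear models, proportional-odds
# ordinal models, Kronecker-structured variance-component models, and
# generalized linear mixed models. Each constructor validates its inputs
# fully so that simulate() can assume a well-formed model.

GLM_FAMILIES <- c(
  "normal", "bernoulli", "binomial", "poisson",
  "negative_binomial", "gamma", "exponential"
)

# Validated family/link pairings; anything else is rejected up front so an
# inverse link can never push a mean outside the family's domain silently.
VALID_LINKS <- list(
  normal = c("identity", "log", "inverse"),
  bernoulli = c("logit", "probit", "cloglog"),
  binomial = c("logit", "probit", "cloglog"),
  poisson = c("log", "sqrt"),
  negative_binomial = "log",
  gamma = c("log", "inverse"),
  exponential = c("log", "inverse")
)

check_dist_link <- function(dist, link) {
  dist <- match.arg(dist, GLM_FAMILIES)
  ok <- VALID_LINKS[[dist]]
  if (!link %in% ok) {
    stop(
      "link '", link, "' is not supported for family '", dist,
      "' (supported: ", paste(ok, collapse = ", "), ")",
      call. = FALSE
    )
  }
  list(dist = dist, link = link)
}

linkinv_fun <- function(link) stats::make.link(link)$linkinv

# CDF and density of the latent distribution implied by an ordinal link.
ordinal_link_funs <- function(link) {
  switch(link,
    logit = list(cdf = stats::plogis, pdf = stats::dlogis),
    probit = list(cdf = stats::pnorm, pdf = stats::dnorm),
    cloglog = list(
      cdf = function(x) -expm1(-exp(pmin(x, 700))),
      pdf = function(x) exp(pmin(x - exp(pmin(x, 700)), 700))
    ),
    stop("ordinal link must be one of logit, probit, cloglog", call. = FALSE)
  )
}

as_design <- function(X, n = NULL, what = "X") {
  if (is.null(X)) {
    if (is.null(n)) stop(what, " or n must be given", call. = FALSE)
    return(matrix(0, n, 0))
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop(what, " must be finite", call. = FALSE)
  X
}

# Linear predictor Xb (+ Gg); works for vector or matrix coefficients.
linear_predictor <- function(X, beta, G = NULL, gamma = NULL) {
  eta <- X %*% beta
  if (!is.null(G) && !is.null(gamma)) {
    eta <- eta + as.matrix(G) %*% gamma
  }
  eta
}

#' Generalized linear trait model
#'
#' Specifies the generative law \eqn{y_i \sim \mathrm{dist}(g^{-1}(\eta_i))}
#' with linear predictor \eqn{\eta = X\beta + G\gamma}: non-genetic
#' covariates \code{X} with coefficients \code{beta}, optional genotype
#' dosages \code{G} with genetic effects \code{gamma}.
#'
#' Family-specific nuisance parameters: \code{sd} (residual standard
#' deviation, normal), \code{trials} (binomial, where the link acts on
#' the per-trial success probability so the mean is
#' \eqn{\mathrm{trials} \cdot p}), \code{dispersion} (negative binomial,
#' variance \eqn{\mu + \mu^2/r}), \code{shape} (gamma, with rate
#' \eqn{\alpha/\mu}). The exponential family has mean
#' \eqn{\mu = 1/\mathrm{rate}}.
#'
#' @param X n x p matrix of non-genetic predictors (no intercept is added;
#'   include a constant column if wanted).
#' @param beta Coefficient vector of length p.
#' @param G Optional n x k matrix (or length-n vector) of genotype dosages.
#' @param gamma Optional genetic effect vector of length k.
#' @param dist Response family, one of \code{"normal"}, \code{"bernoulli"},
#'   \code{"binomial"}, \code{"poisson"}, \code{"negative_binomial"},
#'   \code{"gamma"}, \code{"exponential"}.
#' @param link Link function; only pairings valid for the family are
#'   accepted (see \code{phenosim:::VALID_LINKS}).
#' @param sd,trials,dispersion,shape Family-specific nuisance parameters.
#' @return An object of class \code{glm_trait}.
#' @export
#' @examples
#' m <- glm_trait(cbind(1, rnorm(10)), beta = c(1, 0.5), dist = "poisson", link = "log")
#' simulate(m, seed = 1)
glm_trait <- function(X, beta, G = NULL, gamma = NULL,
                      dist = "normal", link = "identity",
                      sd = 1, trials = NULL, dispersion = NULL, shape = NULL) {
  dl <- check_dist_link(dist, link)
  X <- as_design(X)
  beta <- as.numeric(beta)
  if (ncol(X) != length(beta)) {
    stop("length(beta) must equal ncol(X)", call. = FALSE)
  }
  n <- nrow(X)
  if (!is.null(G)) {
    G <- as_design(G, what = "G")
    if (nrow(G) != n) stop("G must have the same number of rows as X", call. = FALSE)
    gamma <- as.numeric(gamma)
    if (ncol(G) != length(gamma)) {
      stop("length(gamma) must equal ncol(G)", call. = FALSE)
    }
  } else if (!is.null(gamma)) {
    stop("gamma given without G", call. = FALSE)
  }
  aux <- switch(dl$dist,
    normal = {
      if (!is_number(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
      list(sd = sd)
    },
    binomial = {
      if (is.null(trials) || !is_number(trials) || trials < 1) {
        stop("binomial family needs trials >= 1", call. = FALSE)
      }
      list(trials = as.integer(trials))
    },
    negative_binomial = {
      if (is.null(dispersion) || !is_number(dispersion) || dispersion <= 0) {
        stop("negative_binomial family needs dispersion > 0", call. = FALSE)
      }
      list(dispersion = dispersion)
    },
    gamma = {
      if (is.null(shape) || !is_number(shape) || shape <= 0) {
        stop("gamma family needs shape > 0", call. = FALSE)
      }
      list(shape = shape)
    },
    list()
  )
  structure(
    list(
      X = X, beta = beta, G = G, gamma = gamma,
      dist = dl$dist, link = dl$link, aux = aux, n = n
    ),
    class = "glm_trait"
  )
}

#' Proportional-odds ordinal trait model
#'
#' Specifies an ordered-categorical trait with \eqn{J} levels through
#' cumulative probabilities \eqn{\Pr(y_i \le j)} linked to the linear
#' predictor by \eqn{g(\Pr(y_i \le j)) = \theta_j - (X_i'\beta + \gamma G_i)},
#' \eqn{j = 1, \dots, J-1}, where the nondecreasing intercepts
#' \eqn{\theta_1 \le \dots \le \theta_{J-1}} enforce the category order.
#' A positive \eqn{\gamma} shifts probability mass toward higher (more
#' severe) categories; on the logit link \eqn{e^\gamma} is the per-allele
#' cumulative odds ratio.
#'
#' @param X n x p matrix of non-genetic predictors (no intercept column;
#'   intercepts live in \code{theta}).
#' @param beta Coefficient vector of length p.
#' @param theta Nondecreasing vector of J-1 category intercepts.
#' @param G Optional length-n dosage vector for a single SNP.
#' @param gamma Optional scalar genetic effect.
#' @param link One of \code{"logit"} (proportional odds, default),
#'   \code{"probit"}, \code{"cloglog"} (proportional hazards).
#' @return An object of class \code{ordinal_trait}.
#' @export
#' @examples
#' m <- ordinal_trait(matrix(rnorm(20), 10), beta = c(0.2, -0.1), theta = c(-1, 0, 1))
#' simulate(m, seed = 1)
ordinal_trait <- function(X, beta, theta, G = NULL, gamma = NULL,
                          link = "logit") {
  ordinal_link_funs(link) # validates link
  theta <- as.numeric(theta)
  if (length(theta) < 1 || is.unsorted(theta)) {
    stop("theta must be a nondecreasing vector of J-1 intercepts", call. = FALSE)
  }
  X <- as_design(X)
  beta <- as.numeric(beta)
  if (ncol(X) != length(beta)) {
    stop("length(beta) must equal ncol(X)", call. = FALSE)
  }
  n <- nrow(X)
  if (!is.null(G)) {
    G <- as.numeric(G)
    if (length(G) != n) stop("G must have length nrow(X)", call. = FALSE)
    if (is.null(gamma) || !is_number(gamma)) {
      stop("gamma must be a single number when G is given", call. = FALSE)
    }
  } else if (!is.null(gamma)) {
    stop("gamma given without G", call. = FALSE)
  }
  structure(
    list(
      X = X, beta = beta, theta = theta, J = length(theta) + 1L,
      G = G, gamma = gamma, link = link, n = n
    ),
    class = "ordinal_trait"
  )
}

#' Variance component (trait covariance, relatedness) pair
#'
#' A pair \eqn{(\Sigma, V)} contributing \eqn{\Sigma \otimes V} to the
#' covariance of \eqn{\mathrm{vec}(Y)}: \code{sigma} is the d x d trait
#' covariance (a scalar for univariate traits) and \code{V} the n x n
#' relatedness matrix (a kinship/GRM matrix or the identity). PSD square
#' roots are factored once at construction and cached, so repeated
#' simulation from the same model never refactors.
#'
#' @param sigma d x d symmetric PSD matrix, or a single nonnegative number.
#' @param V n x n symmetric PSD matrix, or a \code{grm} object.
#' @return An object of class \code{variance_component} with cached
#'   factors \code{L_sigma}, \code{L_V}.
#' @export
#' @examples
#' vc <- variance_component(0.4, diag(5))
variance_component <- function(sigma, V) {
  if (inherits(V, "grm")) V <- V$matrix
  if (is_number(sigma)) sigma <- matrix(sigma, 1, 1)
  sigma <- as.matrix(sigma)
  V <- as.matrix(V)
  L_sigma <- psd_factor(sigma, label = "sigma (trait covariance)")
  L_V <- if (all(L_sigma == 0)) {
    # null component: contributes exactly zero, V's factor is never used
    matrix(0, nrow(V), ncol(V))
  } else {
    psd_factor(V, label = "V (relatedness matrix)")
  }
  structure(
    list(
      sigma = sigma, V = V,
      L_sigma = L_sigma, L_V = L_V,
      d = nrow(sigma), n = nrow(V)
    ),
    class = "variance_component"
  )
}

check_components <- function(components, n, d = NULL) {
  if (!is.list(components) || length(components) < 1) {
    stop("components must be a non-empty list of variance_component objects",
      call. = FALSE
    )
  }
  components <- lapply(components, function(vc) {
    if (!inherits(vc, "variance_component")) {
      stop("each component must be created by variance_component()", call. = FALSE)
    }
    vc
  })
  ns <- vapply(components, `[[`, 0, "n")
  ds <- vapply(components, `[[`, 0, "d")
  if (any(ns != n)) {
    stop("all variance components must have V of dimension n = ", n, call. = FALSE)
  }
  if (length(unique(ds)) != 1 || (!is.null(d) && ds[1] != d)) {
    stop("all variance components must share the trait dimension d",
      call. = FALSE
    )
  }
  components
}

#' Variance-component (linear mixed) trait model
#'
#' Specifies a d-variate normal trait
#' \deqn{Y = XB + G\Gamma + \sum_c E_c, \qquad
#'   \mathrm{cov}(\mathrm{vec}(E_c)) = \Sigma^{(c)} \otimes V^{(c)},}
#' the classical additive-genetic / environmental decomposition when the
#' components are \eqn{(\sigma_A, \Phi)} and \eqn{(\sigma_E, I_n)} with
#' \eqn{\Phi} a kinship or GRM matrix. \code{vec} stacks columns (traits),
#' so \eqn{V} acts on individuals.
#'
#' @param X n x p design matrix of non-genetic predictors.
#' @param B p x d coefficient matrix (a vector of length p when d = 1).
#' @param components Non-empty list of [variance_component()] objects
#'   sharing n and d.
#' @param G Optional n x k genotype dosage matrix (or length-n vector).
#' @param Gamma Optional k x d genetic coefficient matrix (scalar or
#'   vector accepted for k = 1 or d = 1).
#' @return An object of class \code{vcm_trait}.
#' @export
#' @examples
#' phi <- sibship_kinship(5, 2, scale = "relationship")
#' m <- vcm_trait(matrix(1, 10, 1), B = 0,
#'   components = list(variance_component(0.6, phi), variance_component(0.4, diag(10))))
#' simulate(m, seed = 1)
vcm_trait <- function(X, B, components, G = NULL, Gamma = NULL) {
  X <- as_design(X)
  n <- nrow(X)
  d <- if (is.matrix(B)) ncol(B) else components[[1]]$d
  B <- matrix(as.numeric(B), nrow = ncol(X), ncol = d)
  components <- check_components(components, n = n, d = d)
  if (!is.null(G)) {
    G <- as_design(G, what = "G")
    if (nrow(G) != n) stop("G must have the same number of rows as X", call. = FALSE)
    if (is.null(Gamma)) stop("Gamma must accompany G", call. = FALSE)
    Gamma <- matrix(as.numeric(Gamma), nrow = ncol(G), ncol = d)
  } else if (!is.null(Gamma)) {
    stop("Gamma given without G", call. = FALSE)
  }
  structure(
    list(X = X, B = B, G = G, Gamma = Gamma, components = components, n = n, d = d),
    class = "vcm_trait"
  )
}

#' Generalized linear mixed trait model
#'
#' A univariate GLM whose linear predictor carries correlated random
#' effects: \eqn{\eta = X\beta + G\gamma + u} with
#' \eqn{u \sim N(0, \sum_c \sigma^{(c)} V^{(c)})}, and
#' \eqn{y_i \mid u \sim \mathrm{dist}(g^{-1}(\eta_i))} drawn
#' independently. Random effects enter on the linear-predictor scale.
#'
#' @inheritParams glm_trait
#' @param components Non-empty list of [variance_component()] objects with
#'   d = 1.
#' @return An object of class \code{glmm_trait}.
#' @export
#' @examples
#' m <- glmm_trait(matrix(1, 20, 1), beta = 0,
#'   components = list(variance_component(0.25, diag(20))),
#'   dist = "poisson", link = "log")
#' simulate(m, seed = 1)
glmm_trait <- function(X, beta, components, G = NULL, gamma = NULL,
                       dist = "poisson", link = "log",
                       sd = 1, trials = NULL, dispersion = NULL, shape = NULL) {
  base <- glm_trait(X, beta,
    G = G, gamma = gamma, dist = dist, link = link,
    sd = sd, trials = trials, dispersion = dispersion, shape = shape
  )
  components <- check_components(components, n = base$n, d = 1)
  base$components <- components
  class(base) <- "glmm_trait"
  base
}

#' @export
print.glm_trait <- function(x, ...) {
  cat(
    "glm_trait:", x$dist, "family,", x$link, "link, n =", x$n,
    ", p =", ncol(x$X), if (!is.null(x$G)) paste(", k =", ncol(x$G)) else "", "\n"
  )
  invisible(x)
}

#' @export
print.ordinal_trait <- function(x, ...) {
  cat(
    "ordinal_trait:", x$J, "categories,", x$link, "link, n =", x$n,
    ", p =", ncol(x$X), if (!is.null(x$G)) ", 1 SNP" else "", "\n"
  )
  invisible(x)
}

#' @export
print.vcm_trait <- function(x, ...) {
  cat(
    "vcm_trait: n =", x$n, ", d =", x$d, ",",
    length(x$components), "variance components\n"
  )
  invisible(x)
}

#' @export
print.glmm_trait <- function(x, ...) {
  cat(
    "glmm_trait:", x$dist, "family,", x$link, "link, n =", x$n, ",",
    length(x$components), "variance components\n"
  )
  invisible(x)
}
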