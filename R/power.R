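# Monte Carlo power analysis: for each candidate effect size, simulate
# replicate phenotypes from the generative model, analyze each replicate
# with the matched likelihood-ratio test, and report the proportion of
# replicates rejecting the null with a Wilson confidence interval.

#' Configure a Monte Carlo power study
#'
#' The template model carries every ingredient except the genetic effect
#' size: design matrix, genotype vector, intercepts/variance components,
#' and so on. At each grid value \eqn{\gamma} the template is completed,
#' \code{n_reps} phenotype replicates are simulated, and each is analyzed
#' by the chosen likelihood-ratio analyzer (null fit without the SNP
#' column versus alternative fit with it, 1 degree of freedom).
#'
#' Replicate random-number substreams are derived from \code{seed} only
#' (not from the grid position), so all grid points share common random
#' numbers: results for one effect size are unchanged by adding or
#' removing other grid points, and Monte Carlo noise largely cancels in
#' power differences along the curve.
#'
#' @param model_template An [ordinal_trait()] or univariate [vcm_trait()]
#'   model with a genotype vector \code{G}; its \code{gamma} (or
#'   \code{Gamma}) is overwritten by each grid value.
#' @param effect_grid Numeric vector of effect sizes \eqn{\gamma}.
#' @param n_reps Replicates per grid point (default 1000).
#' @param alpha Significance level in (0, 1); default the genome-wide
#'   5e-8. Use 0.05 or 0.01 at desk scale so power is estimable from
#'   hundreds of replicates.
#' @param seed Integer root seed (mandatory; the study is a pure function
#'   of config + seed).
#' @param analyzer \code{"ordinal_lrt"}, \code{"vcm_lrt"}, or a function
#'   \code{function(y, model, config)} returning a p-value (or \code{NA}
#'   for a failed fit).
#' @return An object of class \code{power_study_config}.
#' @export
power_study_config <- function(model_template, effect_grid, n_reps = 1000,
                               alpha = 5e-8, seed, analyzer = NULL) {
  if (!length(effect_grid)) stop("effect_grid must be non-empty", call. = FALSE)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is_number(n_reps) || n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (missing(seed) || !is_number(seed)) {
    stop("seed is mandatory for a power study", call. = FALSE)
  }
  if (is.null(analyzer)) {
    analyzer <- if (inherits(model_template, "ordinal_trait")) {
      "ordinal_lrt"
    } else if (inherits(model_template, "vcm_trait")) {
      "vcm_lrt"
    } else {
      stop("no default analyzer for this model class; supply one", call. = FALSE)
    }
  }
  if (is.character(analyzer)) {
    analyzer <- match.arg(analyzer, c("ordinal_lrt", "vcm_lrt"))
  } else if (!is.function(analyzer)) {
    stop("analyzer must be 'ordinal_lrt', 'vcm_lrt' or a function", call. = FALSE)
  }
  if (is.null(model_template$G)) {
    stop("model_template must carry a genotype vector G to test", call. = FALSE)
  }
  cfg <- structure(
    list(
      model_template = model_template,
      effect_grid = as.numeric(effect_grid),
      n_reps = as.integer(n_reps),
      alpha = alpha,
      seed = as.integer(seed),
      analyzer = analyzer
    ),
    class = "power_study_config"
  )
  if (identical(analyzer, "vcm_lrt")) {
    if (!inherits(model_template, "vcm_trait") || model_template$d != 1) {
      stop("vcm_lrt analyzer requires a univariate vcm_trait template", call. = FALSE)
    }
    cfg$phi <- vcm_component_phi(model_template)
    cfg$rotation <- vcm_rotation(cfg$phi)
  }
  if (identical(analyzer, "ordinal_lrt") &&
    !inherits(model_template, "ordinal_trait")) {
    stop("ordinal_lrt analyzer requires an ordinal_trait template", call. = FALSE)
  }
  cfg
}

# the relatedness matrix the analysis model should use: the first
# component whose V is not (a multiple of) the identity, else the first V
vcm_component_phi <- function(model) {
  for (vc in model$components) {
    offdiag <- vc$V
    diag(offdiag) <- 0
    if (any(offdiag != 0) || stats::var(diag(vc$V)) > 0) {
      return(vc$V)
    }
  }
  model$components[[1]]$V
}

set_template_gamma <- function(model, gamma) {
  if (inherits(model, "ordinal_trait")) {
    model$gamma <- gamma
  } else if (inherits(model, "vcm_trait")) {
    model$Gamma <- matrix(gamma, nrow = ncol(model$G), ncol = model$d)
  } else {
    model$gamma <- rep(gamma, length.out = ncol(model$G))
  }
  model
}

analyze_replicate <- function(y, model, config) {
  if (is.function(config$analyzer)) {
    return(config$analyzer(y, model, config))
  }
  if (config$analyzer == "ordinal_lrt") {
    Xalt <- cbind(model$X, snp = model$G)
    fit0 <- fit_ordinal(y, model$X, link = model$link, compute_se = FALSE)
    fit1 <- fit_ordinal(y, Xalt, link = model$link, compute_se = FALSE)
    if (!fit0$converged || !fit1$converged) {
      return(NA_real_)
    }
    lrt_pvalue(fit0$loglik, fit1$loglik, df = 1)
  } else {
    Xnull <- model$X
    has_const <- ncol(Xnull) > 0 &&
      any(apply(Xnull, 2, function(col) all(col == col[1])))
    if (!has_const) Xnull <- cbind(intercept = 1, Xnull)
    Xalt <- cbind(Xnull, snp = drop(model$G))
    fit0 <- fit_vcm_univariate(y, Xnull, rotation = config$rotation)
    fit1 <- fit_vcm_univariate(y, Xalt, rotation = config$rotation)
    if (!fit0$converged || !fit1$converged) {
      return(NA_real_)
    }
    lrt_pvalue(fit0$loglik, fit1$loglik, df = 1)
  }
}

simulate_replicate <- function(model) {
  if (inherits(model, "vcm_trait")) {
    drop(simulate(model, nsim = 1))
  } else {
    simulate(model, nsim = 1)[, 1]
  }
}

#' Estimate power at one effect size
#'
#' Runs the replicate loop at a single \eqn{\gamma}: simulate, fit null
#' and alternative models, record whether the LRT p-value falls below
#' \eqn{\alpha}. Replicates whose fits fail to converge are excluded from
#' the denominator and counted in \code{n_failed}; a warning is attached
#' when more than 5\% fail.
#'
#' @param config A [power_study_config()].
#' @param gamma Effect size at which to complete the template.
#' @param keep_pvalues If \code{TRUE}, the replicate p-values are attached
#'   to the result as attribute \code{"pvalues"} (useful for calibration
#'   diagnostics such as a uniformity test under the null).
#' @return One-row data frame: \code{effect_size}, \code{n_reps},
#'   \code{n_used}, \code{n_failed}, \code{rejections}, \code{power},
#'   \code{ci_low}, \code{ci_high}.
#' @export
estimate_power <- function(config, gamma, keep_pvalues = FALSE) {
  stopifnot(inherits(config, "power_study_config"))
  model <- set_template_gamma(config$model_template, gamma)
  seeds <- derive_seeds(config$seed, config$n_reps)
  pvals <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    set.seed(seeds[r])
    y <- simulate_replicate(model)
    pvals[r] <- tryCatch(analyze_replicate(y, model, config),
      error = function(e) NA_real_
    )
  }
  used <- !is.na(pvals)
  n_used <- sum(used)
  n_failed <- config$n_reps - n_used
  if (n_failed > 0.05 * config$n_reps) {
    warning(
      "more than 5% of replicates failed to converge at gamma = ", gamma,
      " (", n_failed, "/", config$n_reps, ")"
    )
  }
  rej <- sum(pvals[used] < config$alpha)
  pw <- if (n_used > 0) rej / n_used else NA_real_
  ci <- if (n_used > 0) wilson_interval(rej, n_used) else c(NA_real_, NA_real_)
  out <- data.frame(
    effect_size = gamma,
    n_reps = config$n_reps,
    n_used = n_used,
    n_failed = n_failed,
    rejections = rej,
    power = pw,
    ci_low = unname(ci[1]),
    ci_high = unname(ci[2])
  )
  if (keep_pvalues) attr(out, "pvalues") <- pvals
  out
}

#' Estimate a power curve over an effect-size grid
#'
#' Maps [estimate_power()] over \code{effect_grid} and attaches the
#' x-axis transform used for plotting: the per-allele odds ratio
#' \eqn{e^\gamma} for ordinal models, or the proportion of variance
#' explained ([pve()]) for variance-component models (MAF taken from the
#' template's genotype vector; total variance defaults to
#' \eqn{\sigma_A + \sigma_E + \gamma^2 2p(1-p)}).
#'
#' @param config A [power_study_config()].
#' @return Data frame of class \code{power_result}, one row per grid
#'   point, with an \code{odds_ratio} or \code{pve} column.
#' @export
power_curve <- function(config) {
  stopifnot(inherits(config, "power_study_config"))
  rows <- lapply(config$effect_grid, function(g) estimate_power(config, g))
  out <- do.call(rbind, rows)
  if (inherits(config$model_template, "ordinal_trait")) {
    out$odds_ratio <- exp(out$effect_size)
  } else if (inherits(config$model_template, "vcm_trait")) {
    gvec <- drop(config$model_template$G)
    maf <- mean(gvec) / 2
    maf <- min(maf, 1 - maf)
    base_var <- sum(vapply(
      config$model_template$components,
      function(vc) vc$sigma[1, 1], 0
    ))
    out$pve <- vapply(out$effect_size, function(g) {
      if (g == 0) 0 else pve(g, maf, base_var + g^2 * 2 * maf * (1 - maf))
    }, 0)
  }
  class(out) <- c("power_result", "data.frame")
  attr(out, "alpha") <- config$alpha
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(
    "Monte Carlo power estimates (alpha =",
    format(attr(x, "alpha")), ")\n"
  )
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a power curve
#'
#' Power against the transformed effect size (odds ratio or PVE when
#' available, raw effect size otherwise), with Wilson interval bars.
#'
#' @param x A \code{power_result} from [power_curve()].
#' @param xlab,ylab,... Passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.power_result <- function(x, xlab = NULL, ylab = "Estimated power", ...) {
  xs <- if (!is.null(x$odds_ratio)) {
    if (is.null(xlab)) xlab <- "Odds ratio"
    x$odds_ratio
  } else if (!is.null(x$pve)) {
    if (is.null(xlab)) xlab <- "Proportion of variance explained"
    x$pve
  } else {
    if (is.null(xlab)) xlab <- "Effect size"
    x$effect_size
  }
  graphics::plot(xs, x$power,
    type = "b", pch = 16, ylim = c(0, 1),
    xlab = xlab, ylab = ylab, ...
  )
  graphics::arrows(xs, x$ci_low, xs, x$ci_high,
    angle = 90, code = 3, length = 0.03
  )
  invisible(x)
}

#' Proportion of variance explained by a SNP
#'
#' Converts an effect size and minor allele frequency into the proportion
#' of trait variance explained, \eqn{\gamma^2 \cdot 2p(1-p) /
#' \sigma^2_{\mathrm{total}}}, using the Hardy-Weinberg genotype variance
#' \eqn{2p(1-p)}.
#'
#' @param gamma Additive effect size per minor allele.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param total_var Total trait variance, positive.
#' @return The proportion (not a percentage).
#' @export
#' @examples
#' pve(0.065, 0.23, 1)
pve <- function(gamma, maf, total_var) {
  if (!is.numeric(maf) || any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.numeric(total_var) || any(total_var <= 0)) {
    stop("total_var must be positive", call. = FALSE)
  }
  gamma^2 * 2 * maf * (1 - maf) / total_var
}
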