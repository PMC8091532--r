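# Internal numeric helpers shared across modules.

#' Wilson score interval for a binomial proportion
#'
#' Computes the Wilson 95\% (or other level) confidence interval for a
#' rejection proportion, the interval attached to every power estimate.
#'
#' @param x Number of successes (rejections).
#' @param n Number of trials (replicates).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector \code{c(low, high)}.
#' @export
#' @examples
#' wilson_interval(50, 1000)
wilson_interval <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# Symmetric PSD square root factor L with L %*% t(L) = M.
# Eigenvalues in [-tol, 0) are clipped to zero; more negative is an error.
# `label` names the offending matrix in error messages.
psd_factor <- function(M, tol = 1e-8, label = "matrix") {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) {
    stop(label, " must be square", call. = FALSE)
  }
  if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M)))) {
    stop(label, " must be symmetric", call. = FALSE)
  }
  n <- nrow(M)
  if (n == 0) {
    return(matrix(0, 0, 0))
  }
  off <- M
  diag(off) <- 0
  if (all(off == 0)) {
    # diagonal fast path (identity and scalar components are common)
    d <- diag(M)
    if (any(d < -tol)) {
      stop(label, " is not positive semidefinite", call. = FALSE)
    }
    return(diag(sqrt(pmax(d, 0)), n))
  }
  e <- eigen(M, symmetric = TRUE)
  scale <- max(1, max(abs(e$values)))
  if (min(e$values) < -tol * scale) {
    stop(label, " is not positive semidefinite (min eigenvalue ",
      format(min(e$values)), ")",
      call. = FALSE
    )
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Check a value is a single finite number.
is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Deterministic per-replicate seeds derived from one root seed.
# Restores the caller's RNG state so seed derivation is side-effect free.
derive_seeds <- function(seed, n) {
  stopifnot(is_number(seed), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}
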