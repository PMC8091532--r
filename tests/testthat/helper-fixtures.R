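# Shared in-code fixtures for the test suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk.

# random dosage matrix with controllable missingness, already normalized
# to minor-allele orientation by the constructor
random_genotypes <- function(n, S, missing_rate = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(c(0L, 1L, 2L), n * S, replace = TRUE), n, S)
  if (missing_rate > 0) {
    d[runif(n * S) < missing_rate] <- NA_integer_
  }
  genotype_matrix(d)
}

# brute-force GRM: literal triple-loop evaluation of the realized
# relatedness formula, with the same MAF filter and HWE-mode imputation
naive_grm <- function(g, maf_threshold = 0.01) {
  p <- minor_allele_frequencies(g)
  keep <- which(!is.na(p) & p > maf_threshold)
  d <- as_dosage(g)[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(d)
  S <- length(keep)
  for (k in seq_len(S)) {
    miss <- is.na(d[, k])
    if (any(miss)) d[miss, k] <- hwe_impute_value(p[k])
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(S)) {
        acc <- acc + (d[i, k] - 2 * p[k]) * (d[j, k] - 2 * p[k]) /
          (2 * p[k] * (1 - p[k]))
      }
      M[i, j] <- acc / (2 * S)
    }
  }
  M
}

# dense multivariate-normal log-density, the oracle for the rotated
# variance-component likelihood
dense_mvn_loglik <- function(y, mean, Sigma) {
  n <- length(y)
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# small standard sibship VCM model used across fitter/power tests
sibship_vcm_model <- function(n_families, sibs = 4, sigma_a = 0.4,
                              sigma_e = 0.6, maf = 0.23, gamma = 0,
                              seed = 99) {
  set.seed(seed)
  n <- n_families * sibs
  phi <- sibship_kinship(n_families, sibs, scale = "relationship")
  g <- rbinom(n, 2, maf)
  vcm_trait(matrix(1, n, 1),
    B = 0,
    components = list(
      variance_component(sigma_a, phi),
      variance_component(sigma_e, diag(n))
    ),
    G = g, Gamma = gamma
  )
}
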