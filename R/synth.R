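# Synthetic genotype generators: unrelated samples under Hardy-Weinberg
# equilibrium, and sibships by single-generation gene dropping. SNPs are
# unlinked (no LD, no recombination map); realism is limited to allele
# frequencies and relatedness structure.

check_maf_vector <- function(maf) {
  if (!is.numeric(maf) || length(maf) < 1 ||
    any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must be a numeric vector with entries in (0, 0.5]", call. = FALSE)
  }
  maf
}

#' Generate unrelated genotypes under Hardy-Weinberg equilibrium
#'
#' Draws each genotype independently as Binomial(2, p) minor-allele
#' dosages, one frequency per SNP, then masks calls as missing at
#' \code{missing_rate}.
#'
#' @param n Number of samples.
#' @param maf Vector of minor allele frequencies in (0, 0.5], one per SNP.
#' @param missing_rate Probability a call is set missing, in [0, 1).
#' @return A [genotype_matrix()].
#' @export
#' @examples
#' set.seed(1)
#' g <- generate_unrelated(100, maf = c(0.1, 0.3, 0.5))
#' minor_allele_frequencies(g)
generate_unrelated <- function(n, maf, missing_rate = 0) {
  stopifnot(is_number(n), n >= 1)
  check_maf_vector(maf)
  if (!is_number(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  S <- length(maf)
  d <- matrix(stats::rbinom(n * S, 2L, rep(maf, each = n)), nrow = n)
  if (missing_rate > 0) {
    d[stats::runif(n * S) < missing_rate] <- NA_integer_
  }
  genotype_matrix(d)
}

#' Theoretical kinship matrix for a sibship design
#'
#' Block-diagonal kinship for independent full sibships: on the kinship
#' scale, diagonal 0.5 and within-family off-diagonal 0.25 (full sibs);
#' with parents included, parent-offspring pairs are 0.25 and the two
#' founders are unrelated. \code{scale = "relationship"} doubles every
#' entry.
#'
#' @param n_families Number of independent families.
#' @param sibs_per_family Number of full sibs per family.
#' @param include_parents Include the two founders of each family.
#' @param scale \code{"kinship"} (default) or \code{"relationship"}.
#' @return A symmetric PSD matrix with class \code{kinship_matrix} and a
#'   \code{scale} attribute.
#' @export
sibship_kinship <- function(n_families, sibs_per_family,
                            include_parents = FALSE,
                            scale = c("kinship", "relationship")) {
  scale <- match.arg(scale)
  stopifnot(n_families >= 1, sibs_per_family >= 1)
  k <- sibs_per_family
  if (include_parents) {
    # order within family: father, mother, sibs
    m <- k + 2L
    block <- matrix(0.25, m, m)
    block[1, 2] <- block[2, 1] <- 0 # founders unrelated
    diag(block) <- 0.5
  } else {
    block <- matrix(0.25, k, k)
    diag(block) <- 0.5
  }
  M <- kronecker(diag(n_families), block)
  if (scale == "relationship") M <- 2 * M
  structure(M, class = c("kinship_matrix", "matrix", "array"), scale = scale)
}

#' Generate sibship genotypes by gene dropping
#'
#' For each family, two founders receive independent Hardy-Weinberg
#' alleles (each allele Bernoulli(p) per SNP); each sib then inherits one
#' uniformly chosen allele from each parent per SNP (Mendelian
#' transmission, SNPs unlinked). Returns the sib genotypes together with
#' the theoretical kinship matrix of the design.
#'
#' @param n_families Number of independent families.
#' @param sibs_per_family Full sibs per family.
#' @param maf Founder minor allele frequencies in (0, 0.5], one per SNP.
#' @param include_parents If \code{TRUE}, founders are included in the
#'   returned sample (ordered father, mother, sibs within family).
#'   Default \code{FALSE}: sib-only designs keep the kinship blocks exact
#'   and simple.
#' @param kinship If \code{FALSE}, skip building the (dense n x n)
#'   theoretical kinship matrix; useful for very large designs where only
#'   the genotypes are needed.
#' @return List with elements \code{genotypes} (a [genotype_matrix()]) and
#'   \code{kinship} (a [sibship_kinship()] matrix, kinship scale, or
#'   \code{NULL}).
#' @export
#' @examples
#' set.seed(1)
#' fam <- generate_sibships(10, 4, maf = rep(0.3, 50))
#' dim(fam$genotypes)
generate_sibships <- function(n_families, sibs_per_family, maf,
                              include_parents = FALSE, kinship = TRUE) {
  stopifnot(is_number(n_families), n_families >= 1)
  stopifnot(is_number(sibs_per_family), sibs_per_family >= 1)
  check_maf_vector(maf)
  nf <- as.integer(n_families)
  k <- as.integer(sibs_per_family)
  S <- length(maf)
  pm <- rep(maf, each = nf)
  draw_alleles <- function() {
    matrix(stats::rbinom(nf * S, 1L, pm), nrow = nf)
  }
  pa1 <- draw_alleles()
  pa2 <- draw_alleles()
  ma1 <- draw_alleles()
  ma2 <- draw_alleles()
  per_fam <- if (include_parents) k + 2L else k
  n <- nf * per_fam
  d <- matrix(0L, nrow = n, ncol = S)
  offset <- if (include_parents) 2L else 0L
  if (include_parents) {
    d[seq(1L, n, by = per_fam), ] <- pa1 + pa2
    d[seq(2L, n, by = per_fam), ] <- ma1 + ma2
  }
  for (j in seq_len(k)) {
    from_father <- ifelse(matrix(stats::runif(nf * S) < 0.5, nf, S), pa1, pa2)
    from_mother <- ifelse(matrix(stats::runif(nf * S) < 0.5, nf, S), ma1, ma2)
    d[seq(offset + j, n, by = per_fam), ] <- from_father + from_mother
  }
  fam_idx <- rep(seq_len(nf), each = per_fam)
  within <- rep(seq_len(per_fam), times = nf)
  if (include_parents) {
    role <- ifelse(within == 1L, "father",
      ifelse(within == 2L, "mother", sprintf("sib%d", within - 2L))
    )
    father <- ifelse(within > 2L, sprintf("fam%d_father", fam_idx), "0")
    mother <- ifelse(within > 2L, sprintf("fam%d_mother", fam_idx), "0")
  } else {
    role <- sprintf("sib%d", within)
    father <- sprintf("fam%d_father", fam_idx)
    mother <- sprintf("fam%d_mother", fam_idx)
  }
  sample_info <- data.frame(
    fid = sprintf("fam%d", fam_idx),
    iid = sprintf("fam%d_%s", fam_idx, role),
    father = father,
    mother = mother,
    sex = 0L,
    phenotype = -9,
    stringsAsFactors = FALSE
  )
  list(
    genotypes = genotype_matrix(d, sample_info = sample_info),
    kinship = if (kinship) {
      sibship_kinship(nf, k, include_parents = include_parents)
    }
  )
}
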