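# Allele frequencies, Hardy-Weinberg mode imputation and the genetic
# relationship matrix (GRM).

#' Minor allele frequencies
#'
#' Computes, per SNP, the frequency of the minor allele among non-missing
#' genotypes. Because [genotype_matrix()] normalizes orientation at
#' construction, frequencies are in [0, 0.5]; a SNP whose calls are all
#' missing gets \code{NA} (undefined, excluded by downstream filters).
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of length \code{n_snps}, named by SNP ID.
#' @export
minor_allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- as_dosage(g)
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  # guard against residual > 0.5 from unnormalized construction
  p <- pmin(p, 1 - p)
  names(p) <- g$snp_info$snp_id
  p
}

#' Most likely genotype under Hardy-Weinberg equilibrium
#'
#' Returns the minor-allele dosage maximizing the HWE genotype
#' probabilities ((1-p)^2, 2p(1-p), p^2). The tie at p = 1/3 between
#' dosages 0 and 1 is resolved to the lower dosage, so the function is a
#' step function: 0 for p <= 1/3, 1 for p > 1/3 (dosage 2 is never the
#' mode for p <= 0.5). Used to impute missing genotypes on the fly during
#' GRM estimation.
#'
#' @param maf Minor allele frequency (vectorized), each in (0, 0.5].
#' @return Integer dosage(s) in \{0, 1\}.
#' @export
#' @examples
#' hwe_impute_value(c(0.2, 0.4))
hwe_impute_value <- function(maf) {
  if (!is.numeric(maf) || any(!is.finite(maf)) ||
    any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  p0 <- (1 - maf)^2
  p1 <- 2 * maf * (1 - maf)
  p2 <- maf^2
  out <- integer(length(maf))
  out[p1 > p0] <- 1L
  out[p2 > pmax(p0, p1)] <- 2L # unreachable for maf <= 0.5; kept for clarity
  out
}

#' Estimate the genetic relationship matrix (GRM)
#'
#' Computes the realized-relatedness matrix
#' \deqn{\hat\Phi_{ij} = \frac{1}{2S} \sum_{k=1}^S
#'   \frac{(G_{ik} - 2p_k)(G_{jk} - 2p_k)}{2 p_k (1 - p_k)},}
#' where \eqn{G_{ik} \in \{0,1,2\}} is the minor-allele dosage, \eqn{p_k}
#' the minor allele frequency and \eqn{S} the number of SNPs retained.
#' SNPs with undefined MAF or MAF at or below \code{maf_threshold} are
#' excluded; missing genotypes are imputed as the most likely genotype
#' under HWE ([hwe_impute_value()]).
#'
#' On this scale an unrelated, non-inbred individual has expected diagonal
#' 1/2, i.e. kinship-coefficient scale. \code{scale = "relationship"}
#' returns twice the formula (diagonal about 1), the additive genetic
#' relationship convention.
#'
#' @param g A [genotype_matrix()].
#' @param maf_threshold Exclude SNPs with MAF at or below this value
#'   (default 0.01).
#' @param scale \code{"kinship"} (the formula as written, default) or
#'   \code{"relationship"} (twice the formula).
#' @return An object of class \code{grm}: list with \code{matrix}
#'   (n x n symmetric, dimnames = sample IIDs), \code{sample_ids},
#'   \code{n_snps_used}, \code{maf_threshold}, \code{scale}.
#' @export
compute_grm <- function(g, maf_threshold = 0.01,
                        scale = c("kinship", "relationship")) {
  stopifnot(inherits(g, "genotype_matrix"))
  scale <- match.arg(scale)
  if (!is_number(maf_threshold) || maf_threshold < 0 || maf_threshold >= 0.5) {
    stop("maf_threshold must lie in [0, 0.5)", call. = FALSE)
  }
  p <- minor_allele_frequencies(g)
  keep <- which(!is.na(p) & p > maf_threshold)
  if (length(keep) == 0) {
    stop("no SNP passes the MAF filter (threshold ", maf_threshold, ")",
      call. = FALSE
    )
  }
  d <- as_dosage(g)[, keep, drop = FALSE]
  p <- p[keep]
  S <- length(keep)
  miss <- which(is.na(d))
  if (length(miss)) {
    snp_of <- (miss - 1L) %/% nrow(d) + 1L
    d[miss] <- hwe_impute_value(p)[snp_of]
  }
  Z <- sweep(d, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  M <- tcrossprod(Z) / (2 * S)
  M <- (M + t(M)) / 2
  if (scale == "relationship") M <- 2 * M
  dimnames(M) <- list(g$sample_info$iid, g$sample_info$iid)
  structure(
    list(
      matrix = M,
      sample_ids = g$sample_info$iid,
      n_snps_used = S,
      maf_threshold = maf_threshold,
      scale = scale
    ),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(
    "grm:", nrow(x$matrix), "x", ncol(x$matrix), "(", x$scale, "scale ),",
    x$n_snps_used, "SNPs used, MAF threshold", x$maf_threshold, "\n"
  )
  invisible(x)
}

#' Write a GRM to disk
#'
#' \code{format = "text"} writes a square tab-delimited matrix with a
#' header row of sample IDs. \code{format = "binary"} writes row-major
#' 64-bit floats to \code{file} plus a sidecar \code{<file>.id} with one
#' sample ID per line.
#'
#' @param grm A \code{grm} object from [compute_grm()].
#' @param file Output path.
#' @param format \code{"text"} (default) or \code{"binary"}.
#' @return Invisibly, the path(s) written.
#' @export
write_grm <- function(grm, file, format = c("text", "binary")) {
  stopifnot(inherits(grm, "grm"))
  format <- match.arg(format)
  if (format == "text") {
    utils::write.table(grm$matrix, file,
      quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = TRUE
    )
    invisible(file)
  } else {
    con <- file(file, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(t(grm$matrix)), con, size = 8)
    idfile <- paste0(file, ".id")
    writeLines(grm$sample_ids, idfile)
    invisible(c(file, idfile))
  }
}

#' Read a text-format GRM written by [write_grm()]
#'
#' @param file Path to a tab-delimited square matrix with sample-ID header.
#' @return A symmetric numeric matrix with sample IDs as dimnames.
#' @export
read_grm <- function(file) {
  m <- as.matrix(utils::read.table(file,
    header = TRUE, sep = "\t",
    check.names = FALSE
  ))
  rownames(m) <- colnames(m)
  m
}
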