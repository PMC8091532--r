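# Packed 2-bit genotype container and PLINK 1.9 binary fileset I/O.
#
# Genotypes are held SNP-major in a raw vector using the PLINK 1.9 2-bit
# codes (within each byte the lowest-order pair of bits is the first
# sample): 00 = 0 copies of allele2, 10 = 1 copy, 11 = 2 copies,
# 01 = missing. After construction allele2 is always the minor allele, so
# decoded entries are minor-allele dosages in {0, 1, 2, NA}.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))
PLINK_MODE_SNP_MAJOR <- as.raw(0x01)

# byte -> its four 2-bit codes, precomputed once
.byte_codes <- local({
  b <- 0:255
  cbind(
    bitwAnd(b, 3L),
    bitwAnd(bitwShiftR(b, 2L), 3L),
    bitwAnd(bitwShiftR(b, 4L), 3L),
    bitwAnd(bitwShiftR(b, 6L), 3L)
  )
})
.code_to_dosage <- c(0L, NA_integer_, 1L, 2L) # index = code + 1
.dosage_to_code <- c(1L, 0L, 2L, 3L) # index = dosage + 2 (NA mapped to -1)

# Decode a SNP-major packed buffer into an n x S integer dosage matrix.
decode_packed <- function(bed, n_samples, n_snps) {
  bytes_per_snp <- ceiling(n_samples / 4)
  stopifnot(length(bed) == bytes_per_snp * n_snps)
  if (n_snps == 0L || n_samples == 0L) {
    return(matrix(NA_integer_, n_samples, n_snps))
  }
  codes <- .byte_codes[as.integer(bed) + 1L, , drop = FALSE]
  codes <- matrix(t(codes), nrow = 4L * bytes_per_snp) # (4B) x S, pad rows last
  matrix(.code_to_dosage[codes[seq_len(n_samples), , drop = FALSE] + 1L],
    nrow = n_samples
  )
}

# Encode an n x S dosage matrix ({0,1,2,NA}) into the packed buffer.
# Pad bits beyond n_samples are zero, as the format requires.
encode_packed <- function(dosage) {
  n <- nrow(dosage)
  S <- ncol(dosage)
  bytes_per_snp <- ceiling(n / 4)
  if (S == 0L || bytes_per_snp == 0) {
    return(raw(0))
  }
  codes <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = S)
  d <- dosage
  d[is.na(d)] <- -1L
  if (n > 0L) {
    codes[seq_len(n), ] <- matrix(.dosage_to_code[d + 2L], nrow = n)
  }
  i <- seq(1L, 4L * bytes_per_snp, by = 4L)
  bytes <- codes[i, , drop = FALSE] +
    4L * codes[i + 1L, , drop = FALSE] +
    16L * codes[i + 2L, , drop = FALSE] +
    64L * codes[i + 3L, , drop = FALSE]
  as.raw(bytes) # column-major flatten = SNP-major byte order
}

default_snp_info <- function(S) {
  data.frame(
    chrom = rep("1", S),
    snp_id = if (S > 0) sprintf("snp%d", seq_len(S)) else character(0),
    genetic_pos = rep(0, S),
    bp_pos = seq_len(S),
    allele1 = rep("A", S),
    allele2 = rep("B", S),
    swapped = rep(FALSE, S),
    stringsAsFactors = FALSE
  )
}

default_sample_info <- function(n) {
  data.frame(
    fid = if (n > 0) sprintf("fam%d", seq_len(n)) else character(0),
    iid = if (n > 0) sprintf("ind%d", seq_len(n)) else character(0),
    father = rep("0", n),
    mother = rep("0", n),
    sex = rep(0L, n),
    phenotype = rep(-9, n),
    stringsAsFactors = FALSE
  )
}

#' Construct a packed genotype matrix
#'
#' Builds the package's central genotype container from an integer dosage
#' matrix (samples in rows, SNPs in columns, values 0/1/2/\code{NA}).
#' Genotypes are stored SNP-major in a packed 2-bit buffer, the same layout
#' as the body of a PLINK .bed file, so a biobank-sized matrix occupies one
#' byte per four genotypes.
#'
#' By default each SNP is oriented so that dosages count the minor allele:
#' if the stored allele2 has frequency above 0.5 among non-missing calls,
#' dosages are flipped (2 - dosage) and the allele labels are swapped, with
#' the swap recorded in \code{snp_info$swapped}.
#'
#' @param dosage Integer matrix, n samples x S SNPs, entries in
#'   \{0, 1, 2, NA\}.
#' @param snp_info Optional data frame with columns \code{chrom},
#'   \code{snp_id}, \code{genetic_pos}, \code{bp_pos}, \code{allele1},
#'   \code{allele2} (the .bim columns). Defaults are generated.
#' @param sample_info Optional data frame with columns \code{fid},
#'   \code{iid}, \code{father}, \code{mother}, \code{sex},
#'   \code{phenotype} (the .fam columns). Defaults are generated.
#' @param normalize_minor If \code{TRUE} (default), orient every SNP to
#'   minor-allele dosage as described above.
#' @return An object of class \code{genotype_matrix}.
#' @seealso [read_plink()], [write_plink()], [as_dosage()]
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), nrow = 2))
#' as_dosage(g)
genotype_matrix <- function(dosage, snp_info = NULL, sample_info = NULL,
                            normalize_minor = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) {
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  n <- nrow(dosage)
  S <- ncol(dosage)
  if (is.null(snp_info)) snp_info <- default_snp_info(S)
  if (is.null(sample_info)) sample_info <- default_sample_info(n)
  snp_info <- as.data.frame(snp_info, stringsAsFactors = FALSE)
  sample_info <- as.data.frame(sample_info, stringsAsFactors = FALSE)
  if (nrow(snp_info) != S) stop("snp_info must have one row per SNP", call. = FALSE)
  if (nrow(sample_info) != n) stop("sample_info must have one row per sample", call. = FALSE)
  if (anyDuplicated(snp_info$snp_id)) {
    stop("snp_id values must be unique", call. = FALSE)
  }
  if (anyDuplicated(paste(sample_info$fid, sample_info$iid))) {
    stop("(fid, iid) pairs must be unique", call. = FALSE)
  }
  if (is.null(snp_info$swapped)) snp_info$swapped <- rep(FALSE, S)
  if (normalize_minor && S > 0 && n > 0) {
    freq2 <- colMeans(dosage, na.rm = TRUE) / 2 # allele2 frequency
    flip <- which(!is.nan(freq2) & freq2 > 0.5)
    if (length(flip)) {
      dosage[, flip] <- 2L - dosage[, flip]
      a1 <- snp_info$allele1[flip]
      snp_info$allele1[flip] <- snp_info$allele2[flip]
      snp_info$allele2[flip] <- a1
      snp_info$swapped[flip] <- !snp_info$swapped[flip]
    }
  }
  structure(
    list(
      bed = encode_packed(dosage),
      n_samples = n,
      n_snps = S,
      snp_info = snp_info,
      sample_info = sample_info
    ),
    class = "genotype_matrix"
  )
}

#' Decode a genotype matrix to integer dosages
#'
#' @param g A [genotype_matrix()].
#' @return Integer matrix (samples x SNPs) of minor-allele dosages with
#'   \code{NA} for missing calls; dimnames are sample IIDs and SNP IDs.
#' @export
as_dosage <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- decode_packed(g$bed, g$n_samples, g$n_snps)
  dimnames(d) <- list(g$sample_info$iid, g$snp_info$snp_id)
  d
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "genotype_matrix:", x$n_samples, "samples x", x$n_snps, "SNPs,",
    format(length(x$bed)), "packed bytes\n"
  )
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(x$n_samples, x$n_snps)

#' Read a PLINK 1.9 binary fileset
#'
#' Reads \code{prefix.bed}, \code{prefix.bim} and \code{prefix.fam} into a
#' packed [genotype_matrix()]. The .bed file must be in SNP-major mode
#' (magic bytes \code{0x6C 0x1B}, mode byte \code{0x01}). Each SNP is
#' re-oriented so that dosages count the minor allele (allele2 frequency
#' above 0.5 flips the dosage and swaps allele labels; the swap is recorded
#' in \code{snp_info$swapped}).
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  bim <- if (length(readLines(paths[2], n = 1)) == 0) {
    default_snp_info(0)[, 1:6]
  } else {
    utils::read.table(paths[2],
      header = FALSE, stringsAsFactors = FALSE,
      colClasses = c("character", "character", "numeric", "integer", "character", "character")
    )
  }
  names(bim) <- c("chrom", "snp_id", "genetic_pos", "bp_pos", "allele1", "allele2")
  fam <- if (length(readLines(paths[3], n = 1)) == 0) {
    default_sample_info(0)
  } else {
    utils::read.table(paths[3],
      header = FALSE, stringsAsFactors = FALSE,
      colClasses = c("character", "character", "character", "character", "integer", "numeric")
    )
  }
  names(fam) <- c("fid", "iid", "father", "mother", "sex", "phenotype")
  n <- nrow(fam)
  S <- nrow(bim)
  raw_all <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw_all) < 3 || !identical(raw_all[1:2], PLINK_MAGIC)) {
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1], call. = FALSE)
  }
  if (raw_all[3] != PLINK_MODE_SNP_MAJOR) {
    stop("unsupported .bed mode byte (only SNP-major 0x01 is supported): ",
      paths[1],
      call. = FALSE
    )
  }
  body <- raw_all[-(1:3)]
  expected <- ceiling(n / 4) * S
  if (length(body) != expected) {
    stop(
      ".bed size inconsistent with .fam/.bim: expected ", expected,
      " body bytes for ", n, " samples x ", S, " SNPs, found ", length(body),
      call. = FALSE
    )
  }
  dosage <- decode_packed(body, n, S)
  genotype_matrix(dosage, snp_info = bim, sample_info = fam)
}

#' Write a PLINK 1.9 binary fileset
#'
#' Writes \code{prefix.bed} (SNP-major), \code{prefix.bim} and
#' \code{prefix.fam} such that [read_plink()] on the same prefix reproduces
#' the genotype content exactly.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  con <- file(paths[1], "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(PLINK_MAGIC, PLINK_MODE_SNP_MAJOR, g$bed), con)
  bim <- g$snp_info[, c("chrom", "snp_id", "genetic_pos", "bp_pos", "allele1", "allele2")]
  utils::write.table(bim, paths[2],
    quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  fam <- g$sample_info[, c("fid", "iid", "father", "mother", "sex", "phenotype")]
  utils::write.table(fam, paths[3],
    quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  invisible(paths)
}
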