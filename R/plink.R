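#' Genotype matrix container
#'
#' Holds an `n x p` matrix of allele counts (0/1/2, `NA` for missing) for the
#' counted allele `A1`, together with per-SNP metadata. Allele frequencies are
#' computed from the observed counts unless supplied.
#'
#' @param X Integer or numeric matrix, individuals in rows, SNPs in columns.
#' @param info `data.frame` with columns `snp_id, chrom, bp, A1, A2` (and
#'   optionally `cm`). Defaults are generated when omitted.
#' @param freq Optional per-SNP frequency of `A1`; computed from `X` otherwise.
#' @return A list of class `genotype_matrix` with elements `X`, `info`, `freq`.
#' @export
genotype_matrix <- function(X, info = NULL, freq = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(info)) {
    info <- data.frame(snp_id = paste0("snp", seq_len(p)),
                       chrom = "1",
                       bp = as.integer(seq_len(p) * 10000L),
                       A1 = "A", A2 = "G",
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(info) == p,
            all(c("snp_id", "chrom", "bp", "A1", "A2") %in% names(info)))
  if (is.null(freq)) freq <- colMeans(X, na.rm = TRUE) / 2
  structure(list(X = X, info = info, freq = as.numeric(freq)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$X), " individuals x ", ncol(x$X), " SNPs\n",
      sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$X)

#' Centred (optionally scaled) dosage matrix
#'
#' Mean-imputes missing genotypes per SNP, centres each column, and optionally
#' scales to unit variance. This is the matrix the model equations refer to.
#'
#' @param geno A [genotype_matrix()].
#' @param scale Scale columns to unit sample variance? Default FALSE.
#' @return A numeric matrix.
#' @export
centred_dosage <- function(geno, scale = FALSE) {
  X <- geno$X
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  X <- sweep(X, 2L, colMeans(X), "-")
  if (scale) {
    sd <- sqrt(colSums(X^2) / (nrow(X) - 1L))
    if (any(sd == 0)) stop("monomorphic SNP cannot be scaled: ",
                           geno$info$snp_id[which(sd == 0)[1L]], call. = FALSE)
    X <- sweep(X, 2L, sd, "/")
  }
  X
}

# PLINK 1 .bed 2-bit codes (SNP-major): 00 hom A1 (2 copies), 01 missing,
# 10 het, 11 hom A2 (0 copies).
.bed_decode <- local({
  tab <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
  code <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (byte in 0:255) {
    for (k in 0:3) {
      two <- bitwAnd(bitwShiftR(byte, 2L * k), 3L)
      tab[byte + 1L, k + 1L] <- code[[as.character(two)]]
    }
  }
  tab
})

#' Read a PLINK bed/bim/fam fileset
#'
#' Minimal reader for PLINK 1 binary genotypes (SNP-major, magic bytes
#' `0x6c 0x1b 0x01`). Counts copies of the bim `A1` allele; missing genotypes
#' become `NA`.
#'
#' @param prefix Path prefix; `prefix.bed/.bim/.fam` must exist.
#' @return A [genotype_matrix()]; individual ids are kept in attribute `"fam"`.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp",
                                         "A1", "A2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pid", "mid",
                                         "sex", "pheno"))
  n <- nrow(fam)
  p <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed_path, "raw", n = 3L + p * bytes_per_snp)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file: bad magic bytes", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  if (length(raw) != 3L + p * bytes_per_snp) {
    stop("truncated .bed file: expected ", 3L + p * bytes_per_snp,
         " bytes, got ", length(raw), call. = FALSE)
  }
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bytes_per_snp, ncol = p)
  X <- matrix(NA_integer_, nrow = n, ncol = p)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4L, length.out = bytes_per_snp)
    rows <- rows[rows <= n]
    nb <- length(rows)
    if (nb > 0L) {
      X[rows, ] <- .bed_decode[body[seq_len(nb), , drop = FALSE] + 1L, k]
    }
  }
  info <- bim[, c("snp_id", "chrom", "bp", "A1", "A2", "cm")]
  g <- genotype_matrix(X, info = info)
  attr(g, "fam") <- fam
  g
}

#' Write a PLINK bed/bim/fam fileset
#'
#' @param geno A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @param pheno Optional phenotype vector for the .fam file (default -9).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, pheno = NULL) {
  X <- geno$X
  n <- nrow(X)
  p <- ncol(X)
  info <- geno$info
  cm <- if (!is.null(info$cm)) info$cm else 0
  bim <- data.frame(info$chrom, info$snp_id, cm, info$bp, info$A1, info$A2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (is.null(pheno)) pheno <- rep(-9, n)
  fam <- data.frame(paste0("F", seq_len(n)), paste0("I", seq_len(n)),
                    0L, 0L, 0L, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  # genotype count -> 2-bit code
  code <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4L - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(p)) {
    x <- X[, j]
    v <- ifelse(is.na(x), 1L, code[as.character(x)])
    if (pad > 0L) v <- c(v, rep(0L, pad))   # padding bits are zero
    m <- matrix(v, nrow = 4L)
    byte <- m[1L, ] + bitwShiftL(m[2L, ], 2L) + bitwShiftL(m[3L, ], 4L) +
      bitwShiftL(m[4L, ], 6L)
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}
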