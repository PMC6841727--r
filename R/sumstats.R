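#' Read GWAS summary statistics in COJO/.ma format
#'
#' Parses a whitespace-delimited summary-statistics table with the 8-column
#' header `SNP A1 A2 freq b se p N` (the de facto COJO-style convention):
#' per-SNP marginal least-squares effect `b` of allele `A1`, its standard
#' error, Wald p-value and the sample size used for that SNP. Optional
#' `chr`/`bp` columns (any case) are carried through when present; they are
#' needed only for region-based QC.
#'
#' Rows with non-numeric or invariant-violating `b`, `se`, `freq`, `p` or `N`
#' (`se <= 0`, `freq` outside (0,1), `N < 1`, `p` outside (0,1]) are dropped
#' with a warning giving the count.
#'
#' @param path Path to the whitespace-delimited file with header.
#' @return A `data.frame` of class `summary_dataset` with columns
#'   `snp_id, A1, A2, freq, b, se, p, n` (plus `chrom`, `bp` when supplied).
#' @export
read_ma <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("snp", "a1", "a2", "freq", "b", "se", "p", "n")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("summary-statistics file is missing required column(s): ",
         paste(toupper(missing_cols), collapse = ", "), call. = FALSE)
  }
  ds <- data.frame(
    snp_id = raw$snp,
    A1 = toupper(raw$a1),
    A2 = toupper(raw$a2),
    freq = suppressWarnings(as.numeric(raw$freq)),
    b = suppressWarnings(as.numeric(raw$b)),
    se = suppressWarnings(as.numeric(raw$se)),
    p = suppressWarnings(as.numeric(raw$p)),
    n = suppressWarnings(as.numeric(raw$n)),
    stringsAsFactors = FALSE
  )
  if ("chr" %in% names(raw)) ds$chrom <- raw$chr
  if ("chrom" %in% names(raw)) ds$chrom <- raw$chrom
  if ("bp" %in% names(raw)) ds$bp <- suppressWarnings(as.integer(raw$bp))

  bad <- !is.finite(ds$b) | !is.finite(ds$se) | !is.finite(ds$n) |
    !is.finite(ds$freq) | !is.finite(ds$p) |
    ds$se <= 0 | ds$n < 1 | ds$freq <= 0 | ds$freq >= 1 | ds$p <= 0 | ds$p > 1
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: non-numeric fields or invariant ",
            "violations (se > 0, freq in (0,1), p in (0,1], N >= 1)",
            call. = FALSE)
    ds <- ds[!bad, , drop = FALSE]
  }
  dup <- unique(ds$snp_id[duplicated(ds$snp_id)])
  if (length(dup) > 0L) {
    stop("duplicate SNP id(s) in summary statistics: ",
         paste(utils::head(dup, 10L), collapse = ", "),
         if (length(dup) > 10L) ", ..." else "", call. = FALSE)
  }
  rownames(ds) <- NULL
  class(ds) <- c("summary_dataset", "data.frame")
  ds
}

#' Construct a summary dataset from vectors
#'
#' Convenience constructor enforcing the `summary_dataset` invariants
#' (no duplicate ids, `freq` in (0,1), `se > 0`, `n >= 1`).
#'
#' @param snp_id,A1,A2,freq,b,se,p,n Per-SNP vectors, recycled to equal length.
#' @param chrom,bp Optional chromosome labels and 1-based positions.
#' @return A `summary_dataset` data frame.
#' @export
summary_dataset <- function(snp_id, A1, A2, freq, b, se,
                            p = rep(1, length(snp_id)), n,
                            chrom = NULL, bp = NULL) {
  ds <- data.frame(snp_id = as.character(snp_id), A1 = toupper(A1),
                   A2 = toupper(A2), freq = as.numeric(freq),
                   b = as.numeric(b), se = as.numeric(se),
                   p = as.numeric(p), n = as.numeric(n),
                   stringsAsFactors = FALSE)
  if (!is.null(chrom)) ds$chrom <- as.character(chrom)
  if (!is.null(bp)) ds$bp <- as.integer(bp)
  if (anyDuplicated(ds$snp_id)) stop("duplicate SNP ids", call. = FALSE)
  if (any(ds$freq <= 0 | ds$freq >= 1)) stop("freq must lie in (0,1)", call. = FALSE)
  if (any(ds$se <= 0)) stop("se must be > 0", call. = FALSE)
  if (any(ds$n < 1)) stop("n must be >= 1", call. = FALSE)
  class(ds) <- c("summary_dataset", "data.frame")
  ds
}

#' Quality-control configuration for summary statistics
#'
#' @param maf_min Minor-allele-frequency threshold; SNPs with
#'   `min(freq, 1 - freq) <= maf_min` are removed. Default 0.01.
#' @param drop_ambiguous Drop strand-ambiguous (A/T and C/G) SNPs. Default TRUE.
#' @param n_lower_pct,n_upper_pct Percentiles (0-100) of the per-SNP sample-size
#'   distribution; SNPs with `n` strictly below the lower or strictly above the
#'   upper percentile are removed (linear-interpolation percentile, R type 7).
#'   Defaults 2.5 and 95, the pre-analysis filter used for meta-analysis
#'   summary sets whose per-SNP `n` varies.
#' @param exclude_regions Optional `data.frame(chrom, start, end)` of regions
#'   (1-based inclusive start, half-open end) to remove, e.g. long-range LD
#'   regions such as the MHC. Requires `chrom`/`bp` columns in the dataset.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, drop_ambiguous = TRUE,
                      n_lower_pct = 2.5, n_upper_pct = 95,
                      exclude_regions = NULL) {
  stopifnot(n_lower_pct >= 0, n_upper_pct <= 100, n_lower_pct < n_upper_pct)
  structure(list(maf_min = maf_min, drop_ambiguous = drop_ambiguous,
                 n_lower_pct = n_lower_pct, n_upper_pct = n_upper_pct,
                 exclude_regions = exclude_regions),
            class = "qc_config")
}

ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Filter summary statistics by MAF, strand ambiguity, sample size and region
#'
#' Applies, in order: MAF filter (`min(freq, 1-freq) <= maf_min` removed),
#' strand-ambiguous allele-pair removal, per-SNP sample-size percentile filter
#' (strictly outside `[n_lower_pct, n_upper_pct]` percentiles removed; linear
#' interpolation percentiles of the `n` values surviving the earlier rules), and
#' exclusion regions. Inconsistent per-SNP sample sizes are a known source of
#' Gibbs-sampler divergence for summary-data models, which is why the
#' percentile rule is part of standard QC here.
#'
#' @param ds A `summary_dataset`.
#' @param cfg A [qc_config()].
#' @return The filtered `summary_dataset`; attribute `"qc_counts"` holds the
#'   per-rule removal counts (`maf`, `ambiguous`, `n_percentile`, `region`).
#' @export
qc_filter <- function(ds, cfg = qc_config()) {
  stopifnot(inherits(ds, "summary_dataset"), nrow(ds) > 0L)
  counts <- c(maf = 0L, ambiguous = 0L, n_percentile = 0L, region = 0L)

  keep <- pmin(ds$freq, 1 - ds$freq) > cfg$maf_min
  counts["maf"] <- sum(!keep)
  ds2 <- ds[keep, , drop = FALSE]

  if (isTRUE(cfg$drop_ambiguous) && nrow(ds2) > 0L) {
    amb <- ambiguous_pair(ds2$A1, ds2$A2)
    counts["ambiguous"] <- sum(amb)
    ds2 <- ds2[!amb, , drop = FALSE]
  }

  if (nrow(ds2) > 0L && (cfg$n_lower_pct > 0 || cfg$n_upper_pct < 100)) {
    qs <- stats::quantile(ds2$n, c(cfg$n_lower_pct, cfg$n_upper_pct) / 100,
                          type = 7, names = FALSE)
    outside <- ds2$n < qs[1] | ds2$n > qs[2]
    counts["n_percentile"] <- sum(outside)
    ds2 <- ds2[!outside, , drop = FALSE]
  }

  if (!is.null(cfg$exclude_regions) && nrow(ds2) > 0L) {
    if (is.null(ds2$chrom) || is.null(ds2$bp)) {
      stop("exclude_regions QC needs chrom/bp columns in the dataset",
           call. = FALSE)
    }
    reg <- cfg$exclude_regions
    inside <- rep(FALSE, nrow(ds2))
    for (k in seq_len(nrow(reg))) {
      inside <- inside | (ds2$chrom == as.character(reg$chrom[k]) &
                            ds2$bp >= reg$start[k] & ds2$bp < reg$end[k])
    }
    counts["region"] <- sum(inside)
    ds2 <- ds2[!inside, , drop = FALSE]
  }

  if (nrow(ds2) == 0L) stop("QC removed every SNP", call. = FALSE)
  rownames(ds2) <- NULL
  attr(ds2, "qc_counts") <- counts
  ds2
}

#' Align summary statistics to a reference allele coding
#'
#' Matches SNPs by id against a reference table of `(snp_id, A1, A2, freq)`
#' (typically the LD reference's `info` table). Records whose `A1/A2` equal
#' the reference's `A2/A1` are flipped (`b <- -b`, `freq <- 1 - freq`) so that
#' the effect sign refers to the reference's counted allele; pairs matching
#' neither orientation are dropped. After alignment, SNPs whose frequency
#' differs from the reference by more than `freq_tol` trigger a warning and
#' are dropped when `drop_freq_mismatch` is `TRUE`.
#'
#' @param ds A `summary_dataset`.
#' @param ref A data frame with columns `snp_id, A1, A2, freq`.
#' @param freq_tol Allowed post-alignment `|freq - ref_freq|`. Default 0.2.
#' @param drop_freq_mismatch Drop SNPs failing the frequency check. Default FALSE.
#' @return The aligned `summary_dataset`, in reference order of the retained
#'   SNPs; attribute `"align_counts"` holds counts
#'   (`missing`, `flipped`, `mismatch`, `freq_flagged`).
#' @export
align_to_reference <- function(ds, ref, freq_tol = 0.2,
                               drop_freq_mismatch = FALSE) {
  stopifnot(inherits(ds, "summary_dataset"))
  stopifnot(all(c("snp_id", "A1", "A2", "freq") %in% names(ref)))
  idx <- match(ds$snp_id, ref$snp_id)
  counts <- c(missing = sum(is.na(idx)), flipped = 0L, mismatch = 0L,
              freq_flagged = 0L)
  keep <- !is.na(idx)
  ds2 <- ds[keep, , drop = FALSE]
  r <- ref[idx[keep], , drop = FALSE]

  same <- ds2$A1 == toupper(r$A1) & ds2$A2 == toupper(r$A2)
  swapped <- ds2$A1 == toupper(r$A2) & ds2$A2 == toupper(r$A1)
  counts["mismatch"] <- sum(!same & !swapped)
  counts["flipped"] <- sum(swapped)

  ds2$b[swapped] <- -ds2$b[swapped]
  ds2$freq[swapped] <- 1 - ds2$freq[swapped]
  tmpA1 <- ds2$A1[swapped]
  ds2$A1[swapped] <- ds2$A2[swapped]
  ds2$A2[swapped] <- tmpA1

  ok <- same | swapped
  ds2 <- ds2[ok, , drop = FALSE]
  r <- r[ok, , drop = FALSE]
  if (nrow(ds2) == 0L) stop("no SNP overlaps the reference after alignment",
                            call. = FALSE)

  dfreq <- abs(ds2$freq - r$freq)
  flagged <- is.finite(dfreq) & dfreq > freq_tol
  counts["freq_flagged"] <- sum(flagged)
  if (any(flagged)) {
    warning(sum(flagged), " SNP(s) with |freq - ref freq| > ", freq_tol,
            if (drop_freq_mismatch) " (dropped)" else "", call. = FALSE)
    if (drop_freq_mismatch) ds2 <- ds2[!flagged, , drop = FALSE]
  }
  if (nrow(ds2) == 0L) stop("no SNP overlaps the reference after alignment",
                            call. = FALSE)
  # return in reference order so downstream SNP lists line up with the LD store
  ds2 <- ds2[order(match(ds2$snp_id, ref$snp_id)), , drop = FALSE]
  rownames(ds2) <- NULL
  attr(ds2, "align_counts") <- counts
  class(ds2) <- c("summary_dataset", "data.frame")
  ds2
}

#' Reconstruct the diagonal of X'X from summary statistics
#'
#' For centred (unscaled) genotypes the genotype sum of squares of SNP `j` is
#' recovered from its marginal effect and standard error as
#' `D_jj = 1 / (se_j^2 + b_j^2 / n_j)`; under the scaled-genotype convention
#' `D_jj = n_j`.
#'
#' @param ds A `summary_dataset`.
#' @param scaled Use the scaled-genotype convention (`D_jj = n_j`)?
#'   Default FALSE (centred, per-allele effects).
#' @return Numeric vector of reconstructed `D_jj`, named by SNP id.
#' @export
reconstruct_D <- function(ds, scaled = FALSE) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (any(ds$se <= 0) || any(ds$n <= 0)) {
    stop("reconstruct_D requires se > 0 and n > 0", call. = FALSE)
  }
  D <- if (scaled) ds$n else 1 / (ds$se^2 + ds$b^2 / ds$n)
  bad <- !is.finite(D) | D <= 0
  if (any(bad)) {
    stop("non-finite or non-positive D for SNP(s): ",
         paste(utils::head(ds$snp_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(D, ds$snp_id)
}

#' Reconstruct the sampler's sufficient statistics
#'
#' Builds `D_diag` (see [reconstruct_D()]), the right-hand side
#' `X'y = D_diag * b`, the scalar `y'y` and the consensus sample size. The
#' phenotype is assumed centred and variance-standardised, so `y'y = n_bar`
#' with `n_bar = median(n)`; supply `yty` to override (e.g. when building
#' exact statistics from an in-sample panel).
#'
#' @param ds A `summary_dataset`.
#' @param scaled Scaled-genotype convention flag, as in [reconstruct_D()].
#' @param yty Optional override for the reconstructed `y'y`.
#' @return A list of class `sufficient_stats` with elements
#'   `snp_id, D_diag, Xty, yty, n_bar, scaled, freq`.
#' @export
reconstruct_sufficient <- function(ds, scaled = FALSE, yty = NULL) {
  D <- reconstruct_D(ds, scaled = scaled)
  n_bar <- stats::median(ds$n)
  structure(list(snp_id = ds$snp_id,
                 D_diag = unname(D),
                 Xty = unname(D) * ds$b,
                 yty = if (is.null(yty)) n_bar else yty,
                 n_bar = n_bar,
                 scaled = scaled,
                 freq = ds$freq),
            class = "sufficient_stats")
}

#' Exact sufficient statistics from an in-sample genotype panel
#'
#' Computes `D_jj = x_j'x_j`, `X'y`, `y'y` and `n` exactly from a centred
#' genotype panel and a centred phenotype. Used to verify the summary-data
#' sampler against the individual-level sampler, for which the two are
#' algebraically equivalent when the full in-sample LD matrix is supplied.
#'
#' @param geno A [genotype_matrix()].
#' @param y Phenotype vector (will be centred).
#' @param scaled Centre-and-scale the genotype columns first? Default FALSE.
#' @return A `sufficient_stats` list.
#' @export
exact_sufficient_stats <- function(geno, y, scaled = FALSE) {
  X <- centred_dosage(geno, scale = scaled)
  y <- y - mean(y)
  D <- colSums(X^2)
  structure(list(snp_id = geno$info$snp_id,
                 D_diag = unname(D),
                 Xty = unname(drop(crossprod(X, y))),
                 yty = sum(y^2),
                 n_bar = length(y),
                 scaled = scaled,
                 freq = geno$freq),
            class = "sufficient_stats")
}

#' @export
print.sufficient_stats <- function(x, ...) {
  cat("sufficient_stats: ", length(x$D_diag), " SNPs, n_bar = ", x$n_bar,
      ", y'y = ", format(x$yty), ", convention = ",
      if (x$scaled) "scaled" else "centred", "\n", sep = "")
  invisible(x)
}

#' Write summary statistics in .ma format
#'
#' @param ds A `summary_dataset`.
#' @param path Output path.
#' @export
write_ma <- function(ds, path) {
  out <- data.frame(SNP = ds$snp_id, A1 = ds$A1, A2 = ds$A2,
                    freq = ds$freq, b = ds$b, se = ds$se, p = ds$p, N = ds$n)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
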