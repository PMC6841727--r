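#' Read an interpolated genetic map file
#'
#' Reads a whitespace-delimited per-chromosome map with header columns
#' `position` (bp), `rate` (cM/Mb) and `map` (cM) — the layout of the
#' interpolated 1000G OMNI maps commonly distributed for LD shrinkage.
#' Column order is detected from the header; files without a header are
#' assumed to be in `position rate map` order.
#'
#' @param path Map file path.
#' @return A `data.frame` of class `genetic_map` with columns `bp, rate, cm`,
#'   sorted by position.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    names(tab) <- tolower(names(tab))
    bp_col <- grep("pos|^bp", names(tab))[1L]
    rate_col <- grep("rate", names(tab))[1L]
    cm_col <- setdiff(grep("map|genetic", names(tab)), rate_col)[1L]
    if (any(is.na(c(bp_col, rate_col, cm_col)))) {
      stop("genetic map header must name position, rate and map columns",
           call. = FALSE)
    }
    tab <- data.frame(bp = tab[[bp_col]], rate = tab[[rate_col]],
                      cm = tab[[cm_col]])
  } else {
    names(tab)[1:3] <- c("bp", "rate", "cm")
  }
  genetic_map(tab$bp, tab$cm, tab$rate)
}

#' Construct a genetic map table
#'
#' @param bp Strictly increasing physical positions (bp).
#' @param cm Non-decreasing genetic positions (cM).
#' @param rate Optional local recombination rate (cM/Mb).
#' @return A `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(bp, cm, rate = NULL) {
  o <- order(bp)
  bp <- as.numeric(bp)[o]
  cm <- as.numeric(cm)[o]
  if (any(diff(bp) <= 0)) stop("map positions must be strictly increasing",
                               call. = FALSE)
  if (any(diff(cm) < 0)) stop("map cM must be non-decreasing", call. = FALSE)
  if (is.null(rate)) {
    rate <- if (length(bp) > 1L) {
      c(diff(cm) / diff(bp) * 1e6, NA_real_)
    } else NA_real_
  } else {
    rate <- as.numeric(rate)[o]
  }
  structure(data.frame(bp = bp, rate = rate, cm = cm),
            class = c("genetic_map", "data.frame"))
}

#' Uniform-rate genetic map
#'
#' A two-row map giving a constant recombination rate over a bp interval;
#' convenient for simulated panels.
#'
#' @param bp_max Last position covered (bp).
#' @param rate_cm_per_mb Constant rate, default 1 cM/Mb.
#' @return A `genetic_map`.
#' @export
uniform_genetic_map <- function(bp_max, rate_cm_per_mb = 1) {
  genetic_map(bp = c(1, bp_max),
              cm = c(0, (bp_max - 1) * rate_cm_per_mb / 1e6),
              rate = c(rate_cm_per_mb, rate_cm_per_mb))
}

#' Interpolate genetic-map positions
#'
#' Piecewise-linear interpolation of the cM coordinate at arbitrary bp
#' positions. Positions outside the map range are extrapolated linearly with
#' the nearest interval's rate.
#'
#' @param bp_positions Vector of physical positions.
#' @param map A [genetic_map()].
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(bp_positions, map) {
  stopifnot(inherits(map, "genetic_map"))
  if (nrow(map) == 0L) stop("empty genetic map", call. = FALSE)
  if (nrow(map) == 1L) {
    rate <- if (is.finite(map$rate[1L])) map$rate[1L] else 0
    return(map$cm[1L] + (bp_positions - map$bp[1L]) * rate / 1e6)
  }
  cm <- stats::approx(map$bp, map$cm, xout = bp_positions, rule = 1)$y
  lo <- bp_positions < map$bp[1L]
  hi <- bp_positions > map$bp[nrow(map)]
  if (any(lo)) {
    slope <- (map$cm[2L] - map$cm[1L]) / (map$bp[2L] - map$bp[1L])
    cm[lo] <- map$cm[1L] + (bp_positions[lo] - map$bp[1L]) * slope
  }
  if (any(hi)) {
    k <- nrow(map)
    slope <- (map$cm[k] - map$cm[k - 1L]) / (map$bp[k] - map$bp[k - 1L])
    cm[hi] <- map$cm[k] + (bp_positions[hi] - map$bp[k]) * slope
  }
  cm
}

#' Shrinkage configuration for the LD estimator
#'
#' @param Ne Effective population size entering the population-scaled
#'   recombination rate; default 11,400 (European-ancestry convention).
#' @param m_map Sample size of the genetic-map reference cohort; default 183
#'   (CEU individuals behind the interpolated 1000G map).
#' @param cutoff Hard threshold below which the shrinkage factor (and hence
#'   the stored LD entry) is set to zero; default 1e-3.
#' @return A list of class `shrink_config`.
#' @export
shrink_config <- function(Ne = 11400, m_map = 183, cutoff = 1e-3) {
  stopifnot(Ne > 0, m_map > 0, cutoff > 0, cutoff < 1)
  structure(list(Ne = Ne, m_map = m_map, cutoff = cutoff),
            class = "shrink_config")
}

#' Off-diagonal LD shrinkage factor
#'
#' Each off-diagonal LD correlation between sites i and j is multiplied by
#' `exp(-rho_ij / (2 * m_map))` with population-scaled recombination rate
#' `rho_ij = 4 * Ne * c_ij`, where `c_ij` is the genetic distance in Morgans
#' (cM / 100, the Wen-Stephens/Li-Stephens convention). Factors below
#' `cutoff` are returned as exactly 0, which is what makes the stored matrix
#' sparse. With the defaults the factor reaches the cutoff at a distance of
#' `-2 * m_map * log(cutoff) / (4 * Ne)` ~= 0.0554 Morgans (~5.5 cM).
#'
#' @param c_ij Genetic distance(s) in Morgans, `>= 0`.
#' @param cfg A [shrink_config()].
#' @return Shrinkage factor(s) in `[0, 1]`.
#' @export
shrink_factor <- function(c_ij, cfg = shrink_config()) {
  if (any(c_ij < 0)) stop("genetic distance must be non-negative",
                          call. = FALSE)
  f <- exp(-4 * cfg$Ne * c_ij / (2 * cfg$m_map))
  f[f < cfg$cutoff] <- 0
  f
}

#' Maximum genetic distance retained by the shrinkage cutoff
#'
#' @param cfg A [shrink_config()].
#' @return Distance in Morgans at which the shrinkage factor equals `cutoff`.
#' @export
shrink_max_distance <- function(cfg = shrink_config()) {
  -2 * cfg$m_map * log(cfg$cutoff) / (4 * cfg$Ne)
}

#' Build a sparse shrunk LD correlation matrix
#'
#' Computes pairwise Pearson correlations between SNPs of one chromosome from
#' a reference genotype panel (missing genotypes mean-imputed per SNP),
#' multiplies each off-diagonal entry by [shrink_factor()] of the pairwise
#' genetic distance, and stores, per SNP, the contiguous window of entries
#' whose shrinkage factor is at or above the cutoff. The diagonal is forced to
#' 1. Because cM positions are monotone in genomic order, each SNP's retained
#' neighbours form one contiguous index range, which is what makes the
#' sampler's right-hand-side update a single short vector operation.
#'
#' @param geno A [genotype_matrix()] for one chromosome, SNPs in genomic order.
#' @param cm Per-SNP genetic position in cM (see [interpolate_cm()]).
#' @param cfg A [shrink_config()].
#' @return A list of class `sparse_ld`: `info` (per-SNP metadata incl.
#'   `window_start`, `window_end`, `nnz`) and `values` (list of per-SNP
#'   numeric windows, including the unit diagonal entry).
#' @export
build_sparse_ld <- function(geno, cm, cfg = shrink_config()) {
  p <- ncol(geno$X)
  stopifnot(length(cm) == p)
  if (is.unsorted(cm)) stop("SNPs must be supplied in genomic (cM) order",
                            call. = FALSE)
  X <- centred_dosage(geno, scale = FALSE)
  ss <- colSums(X^2)
  if (any(ss == 0)) {
    stop("monomorphic SNP in LD panel (filter upstream): ",
         geno$info$snp_id[which(ss == 0)[1L]], call. = FALSE)
  }
  Xs <- sweep(X, 2L, sqrt(ss), "/")        # unit-norm columns -> crossprod = r
  max_d_cm <- shrink_max_distance(cfg) * 100
  values <- vector("list", p)
  # windows are contiguous because cm is monotone
  w_start <- findInterval(cm - max_d_cm, cm, left.open = TRUE) + 1L
  w_end <- findInterval(cm + max_d_cm, cm)
  # chunked BLAS cross-products: one p x chunk correlation slab at a time
  chunk <- max(1L, min(p, as.integer(2^22 / p)))
  for (c0 in seq.int(1L, p, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, p)
    slab <- crossprod(Xs, Xs[, c0:c1, drop = FALSE])
    for (j in c0:c1) {
      idx <- w_start[j]:w_end[j]
      v <- slab[idx, j - c0 + 1L] *
        shrink_factor(abs(cm[idx] - cm[j]) / 100, cfg)
      v[idx == j] <- 1
      values[[j]] <- v
    }
  }
  info <- geno$info
  info$cm <- cm
  info$freq <- geno$freq
  info$window_start <- w_start
  info$window_end <- w_end
  info$nnz <- w_end - w_start + 1L
  structure(list(info = info, values = values), class = "sparse_ld")
}

#' @export
print.sparse_ld <- function(x, ...) {
  cat("sparse_ld: ", nrow(x$info), " SNPs, mean window ",
      round(mean(x$info$nnz), 1), " SNPs, density ",
      signif(sum(x$info$nnz) / nrow(x$info)^2, 3), "\n", sep = "")
  invisible(x)
}

#' Densify a sparse LD matrix (small instances only)
#'
#' @param ld A `sparse_ld`.
#' @return A dense p x p symmetric matrix with unit diagonal.
#' @export
ld_as_matrix <- function(ld) {
  p <- nrow(ld$info)
  B <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- ld$info$window_start[j]:ld$info$window_end[j]
    B[idx, j] <- ld$values[[j]]
  }
  B
}

#' Exact full LD matrix from a panel (no shrinkage, no cutoff)
#'
#' Builds the dense in-sample correlation matrix as a `sparse_ld` whose
#' windows span all SNPs. Used for the equivalence check against the
#' individual-level sampler.
#'
#' @param geno A [genotype_matrix()].
#' @return A `sparse_ld` with full windows.
#' @export
full_ld <- function(geno) {
  X <- centred_dosage(geno, scale = FALSE)
  ss <- colSums(X^2)
  if (any(ss == 0)) stop("monomorphic SNP in LD panel", call. = FALSE)
  Xs <- sweep(X, 2L, sqrt(ss), "/")
  B <- crossprod(Xs)
  diag(B) <- 1
  p <- ncol(B)
  info <- geno$info
  info$cm <- if (!is.null(info$cm)) info$cm else 0
  info$freq <- geno$freq
  info$window_start <- rep(1L, p)
  info$window_end <- rep(p, p)
  info$nnz <- rep(p, p)
  structure(list(info = info, values = lapply(seq_len(p), function(j) B[, j])),
            class = "sparse_ld")
}

ld_magic <- "SLDM1"

#' Write / read the sparse LD store
#'
#' The store is a pair of files: `prefix.info`, a tab-separated text table of
#' per-SNP metadata (id, chrom, bp, cM, alleles, frequency, window bounds,
#' nnz), and `prefix.bin`, the packed windows as little-endian doubles
#' preceded by the magic string, the SNP count and the total value count, and
#' followed by the sum of all values as a checksum. `read_ld(write_ld(x))`
#' reproduces `x` exactly (doubles are stored bitwise).
#'
#' @param ld A `sparse_ld`.
#' @param prefix Path prefix for the two files.
#' @return `prefix` invisibly (`write_ld`); the `sparse_ld` (`read_ld`).
#' @export
write_ld <- function(ld, prefix) {
  stopifnot(inherits(ld, "sparse_ld"))
  if (nrow(ld$info) == 0L) stop("refusing to write an empty LD matrix",
                                call. = FALSE)
  utils::write.table(ld$info, paste0(prefix, ".info"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  vals <- unlist(ld$values, use.names = FALSE)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeChar(ld_magic, con, eos = NULL)
  writeBin(as.numeric(c(nrow(ld$info), length(vals))), con, size = 8L,
           endian = "little")
  writeBin(vals, con, size = 8L, endian = "little")
  writeBin(sum(vals), con, size = 8L, endian = "little")
  invisible(prefix)
}

#' @rdname write_ld
#' @export
read_ld <- function(prefix) {
  info_path <- paste0(prefix, ".info")
  bin_path <- paste0(prefix, ".bin")
  if (!file.exists(info_path) || !file.exists(bin_path)) {
    stop("LD store not found at prefix ", prefix, call. = FALSE)
  }
  info <- utils::read.table(info_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(snp_id = "character",
                                           chrom = "character"))
  con <- file(bin_path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(ld_magic), useBytes = TRUE)
  if (!identical(magic, ld_magic)) stop("corrupt LD store: bad magic",
                                        call. = FALSE)
  hdr <- readBin(con, "double", n = 2L, size = 8L, endian = "little")
  if (length(hdr) != 2L) stop("corrupt LD store: truncated header",
                              call. = FALSE)
  p <- as.integer(hdr[1L])
  n_vals <- as.integer(hdr[2L])
  if (p != nrow(info)) stop("corrupt LD store: info/bin SNP count mismatch",
                            call. = FALSE)
  vals <- readBin(con, "double", n = n_vals, size = 8L, endian = "little")
  if (length(vals) != n_vals) stop("corrupt LD store: truncated values",
                                   call. = FALSE)
  chk <- readBin(con, "double", n = 1L, size = 8L, endian = "little")
  if (length(chk) != 1L || !isTRUE(all.equal(chk, sum(vals), tolerance = 1e-12))) {
    stop("corrupt LD store: checksum mismatch", call. = FALSE)
  }
  nnz <- info$nnz
  if (sum(nnz) != n_vals) stop("corrupt LD store: window sizes do not match",
                               call. = FALSE)
  ends <- cumsum(nnz)
  starts <- ends - nnz + 1L
  values <- lapply(seq_len(p), function(j) vals[starts[j]:ends[j]])
  structure(list(info = info, values = values), class = "sparse_ld")
}
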