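#' Simulate blockwise-LD genotypes
#'
#' Generates an `n x p` panel of 0/1/2 allele counts with controllable
#' linkage disequilibrium: per-SNP minor-allele frequencies are drawn
#' uniformly from `maf_range`; within blocks of `block_size` SNPs two latent
#' AR(1) Gaussian haplotypes (autocorrelation `rho`) are thresholded at the
#' per-SNP MAF quantile and summed; blocks are independent, emulating
#' the blocky correlation structure of real panels. Physical positions are
#' laid out contiguously at 3 kb spacing — the SNP density of a
#' common-variant (HapMap3-like) panel — so blocks of 100 SNPs span ~300 kb,
#' a realistic LD-block scale, and under a uniform 1 cM/Mb map the LD
#' windows implied by the shrinkage cutoff (~5.5 cM) cover thousands of
#' SNPs, as they do at genome scale.
#'
#' @param n Individuals.
#' @param p SNPs.
#' @param block_size SNPs per LD block (default 100).
#' @param rho Latent AR(1) autocorrelation in `[0, 1)` (default 0.9).
#' @param maf_range MAF range, subset of (0, 0.5] (default c(0.05, 0.5)).
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] with metadata and an attribute `"maf"`
#'   holding the generating MAFs.
#' @export
simulate_genotypes <- function(n, p, block_size = 100L, rho = 0.9,
                               maf_range = c(0.05, 0.5), seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  thr <- stats::qnorm(maf)
  X <- matrix(0L, n, p)
  start <- 1L
  while (start <= p) {
    end <- min(start + block_size - 1L, p)
    idx <- start:end
    for (h in 1:2) {
      Z <- matrix(stats::rnorm(n * length(idx)), n, length(idx))
      if (rho > 0 && length(idx) > 1L) {
        w <- sqrt(1 - rho^2)
        for (k in 2:length(idx)) {
          Z[, k] <- rho * Z[, k - 1L] + w * Z[, k]
        }
      }
      X[, idx] <- X[, idx] + (Z < rep(thr[idx], each = n))
    }
    start <- end + 1L
  }
  info <- data.frame(snp_id = sprintf("snp%05d", seq_len(p)),
                     chrom = "1", bp = as.integer(seq_len(p) * 3000L),
                     A1 = "A", A2 = "G", stringsAsFactors = FALSE)
  g <- genotype_matrix(X, info = info)
  attr(g, "maf") <- maf
  g
}

#' Genetic-architecture specification
#'
#' Two modes mirroring the standard simulation designs for this model class:
#' `"bayesr-mixture"` draws the stated numbers of causal variants from
#' `N(0, 0.01 s2)`, `N(0, 0.1 s2)` and `N(0, s2)` (counts in 1:2:1 proportion
#' at full genome scale: 2500/5000/2500); `"single-normal"` draws one causal
#' set from `N(0, s2)`.
#'
#' @param mode `"bayesr-mixture"` or `"single-normal"`.
#' @param counts Per-component causal counts (mixture mode: length 3, small to
#'   large variance; normal mode: length 1).
#' @param weights Variance weights per mixture component (default
#'   `c(0.01, 0.1, 1)`).
#' @param sigma2_beta_base Base effect variance `s2` (default 1).
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(mode = c("bayesr-mixture", "single-normal"),
                              counts = c(2500, 5000, 2500),
                              weights = c(0.01, 0.1, 1),
                              sigma2_beta_base = 1) {
  mode <- match.arg(mode)
  if (mode == "single-normal") {
    stopifnot(length(counts) == 1L)
    weights <- 1
  } else {
    stopifnot(length(counts) == length(weights))
  }
  stopifnot(all(counts >= 0), sigma2_beta_base > 0)
  structure(list(mode = mode, counts = as.integer(counts),
                 weights = as.numeric(weights),
                 sigma2_beta_base = sigma2_beta_base),
            class = "architecture_spec")
}

#' Draw causal effects under an architecture
#'
#' Causal indices are sampled uniformly without replacement among the `p`
#' SNPs; effects for component `k` are drawn from
#' `N(0, weights[k] * sigma2_beta_base)`; all other effects are zero.
#'
#' @param p Number of SNPs.
#' @param arch An [architecture_spec()].
#' @param seed Optional integer seed.
#' @return A list with `beta` (length p), `causal` (indices) and `component`
#'   (label per causal index, parallel to `causal`).
#' @export
simulate_effects <- function(p, arch = architecture_spec(), seed = NULL) {
  stopifnot(sum(arch$counts) <= p)
  if (!is.null(seed)) set.seed(seed)
  beta <- numeric(p)
  total <- sum(arch$counts)
  causal <- if (total > 0L) sample.int(p, total) else integer(0)
  component <- rep.int(seq_along(arch$counts), arch$counts)
  if (total > 0L) {
    sds <- sqrt(arch$weights[component] * arch$sigma2_beta_base)
    beta[causal] <- stats::rnorm(total, 0, sds)
  }
  list(beta = beta, causal = causal, component = component)
}

#' Simulate a quantitative phenotype at a target heritability
#'
#' Genetic values are `g = X_cs beta` on centred-and-scaled genotypes; the
#' residual variance is set to `var(g) (1 - h2) / h2` so the trait
#' heritability is `h2` by construction, and the phenotype is returned
#' centred.
#'
#' @param geno A [genotype_matrix()].
#' @param beta Effect vector on the scaled-genotype scale.
#' @param h2 Target heritability in (0, 1).
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector with attributes `"g"` (genetic values)
#'   and `"h2_realised"` (`var(g)/var(y)`).
#' @export
simulate_phenotype <- function(geno, beta, h2, seed = NULL) {
  stopifnot(h2 > 0, h2 < 1)
  if (all(beta == 0)) {
    stop("all effects are zero: residual scaling to a target h2 is undefined",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  X <- centred_dosage(geno, scale = TRUE)
  g <- drop(X %*% beta)
  var_g <- stats::var(g)
  y <- g + stats::rnorm(length(g), 0, sqrt(var_g * (1 - h2) / h2))
  y <- y - mean(y)
  attr(y, "g") <- g
  attr(y, "h2_realised") <- var_g / stats::var(y)
  y
}

#' Liability-threshold case-control status
#'
#' Cases are individuals whose standardised liability exceeds
#' `t = qnorm(1 - K)` for disease prevalence `K` (e.g. `K = 0.05` gives
#' `t ~= 1.645`).
#'
#' @param liability Standardised liability vector (mean 0, variance 1).
#' @param K Prevalence in (0, 1).
#' @return Integer 0/1 vector (1 = case).
#' @export
simulate_case_control <- function(liability, K) {
  stopifnot(K > 0, K < 1)
  as.integer(liability > stats::qnorm(1 - K))
}

#' Per-SNP least-squares GWAS
#'
#' Simple linear regression of the phenotype on each SNP's allele count in
#' turn: slope, standard error, two-sided Wald p-value (t with n_j - 2 df)
#' and per-SNP sample size excluding missing genotypes. Frequencies are the
#' panel's counted-allele frequencies.
#'
#' @param geno A [genotype_matrix()].
#' @param y Phenotype vector.
#' @return A `summary_dataset` with one row per SNP.
#' @export
run_gwas <- function(geno, y) {
  X <- geno$X
  n_i <- nrow(X)
  stopifnot(length(y) == n_i)
  miss <- is.na(X)
  has_miss <- any(miss)
  if (has_miss) {
    n_j <- n_i - colSums(miss)
    Xz <- X
    Xz[miss] <- 0
    obs <- 1 - miss                       # n x p indicator
    sum_x <- colSums(Xz)
    sum_x2 <- colSums(Xz^2)
    sum_y <- drop(crossprod(obs, y))
    sum_y2 <- drop(crossprod(obs, y^2))
    sum_xy <- drop(crossprod(Xz, y))
  } else {
    n_j <- rep(n_i, ncol(X))
    sum_x <- colSums(X)
    sum_x2 <- colSums(X^2)
    sum_y <- rep(sum(y), ncol(X))
    sum_y2 <- rep(sum(y^2), ncol(X))
    sum_xy <- drop(crossprod(X, y))
  }
  sxx <- sum_x2 - sum_x^2 / n_j
  sxy <- sum_xy - sum_x * sum_y / n_j
  syy <- sum_y2 - sum_y^2 / n_j
  if (any(sxx <= 0)) {
    stop("monomorphic SNP(s) in GWAS panel: ",
         paste(utils::head(geno$info$snp_id[sxx <= 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  b <- sxy / sxx
  rss <- pmax(syy - b * sxy, 0)
  se <- sqrt(rss / (n_j - 2) / sxx)
  se <- pmax(se, 1e-300)   # exact fits: keep the se > 0 invariant
  tstat <- b / se
  pval <- 2 * stats::pt(-abs(tstat), df = n_j - 2)
  pval <- pmax(pval, .Machine$double.xmin)   # keep within (0, 1]
  summary_dataset(snp_id = geno$info$snp_id, A1 = geno$info$A1,
                  A2 = geno$info$A2, freq = geno$freq, b = b, se = se,
                  p = pval, n = n_j, chrom = geno$info$chrom,
                  bp = geno$info$bp)
}

#' One-call simulation of a complete study
#'
#' Convenience wrapper chaining [simulate_genotypes()], [simulate_effects()],
#' [simulate_phenotype()] and optionally [simulate_case_control()] under a
#' single seed, returning everything a downstream analysis needs (panel,
#' truth tables, phenotype).
#'
#' @param n,p,block_size,rho,maf_range As in [simulate_genotypes()].
#' @param arch An [architecture_spec()].
#' @param h2 Target heritability.
#' @param prevalence Optional disease prevalence; when given, the phenotype is
#'   treated as a liability and a binary `status` is added.
#' @param seed Integer seed controlling the whole study.
#' @return A list with `geno`, `y` (quantitative phenotype or liability),
#'   `truth` (`data.frame` of causal index, component, beta) and optionally
#'   `status`.
#' @export
simulate_study <- function(n, p, block_size = 100L, rho = 0.9,
                           maf_range = c(0.05, 0.5),
                           arch = architecture_spec(counts = c(50, 100, 50)),
                           h2 = 0.5, prevalence = NULL, seed = 1L) {
  set.seed(seed)
  geno <- simulate_genotypes(n, p, block_size, rho, maf_range)
  eff <- simulate_effects(p, arch)
  y <- simulate_phenotype(geno, eff$beta, h2)
  out <- list(geno = geno, y = y,
              truth = data.frame(causal = eff$causal,
                                 component = eff$component,
                                 beta = eff$beta[eff$causal]),
              beta = eff$beta)
  if (!is.null(prevalence)) {
    liab <- as.numeric(scale(y))
    out$status <- simulate_case_control(liab, prevalence)
  }
  out
}
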