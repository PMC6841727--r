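#' Run the individual-level BayesR sampler
#'
#' Fits the same mixture-of-normals hierarchical model as [run_sbayesr()]
#' directly on a genotype panel and phenotype, maintaining the residual
#' vector on individuals. With the exact in-sample LD matrix and diagonal
#' supplied to [run_sbayesr()], the two samplers are algebraically equivalent
#' and, given the same seed and fixed update order, produce matching draws —
#' the package's primary correctness check.
#'
#' @param geno A [genotype_matrix()] (or a plain numeric matrix of counts).
#' @param y Phenotype vector; centred internally.
#' @param mix A [mixture_spec()].
#' @param cfg A [chain_config()]; `rhs_check_every` triggers the
#'   maintained-residual consistency diagnostic.
#' @param scaled Centre-and-scale genotype columns? Default FALSE (centred).
#' @return A `posterior_summary` (see [run_sbayesr()]).
#' @export
run_bayesr <- function(geno, y, mix = mixture_spec(), cfg = chain_config(),
                       scaled = FALSE) {
  if (is.matrix(geno)) {
    if (nrow(geno) == 0L || ncol(geno) == 0L) {
      stop("empty genotype matrix", call. = FALSE)
    }
    geno <- genotype_matrix(geno)
  }
  X <- centred_dosage(geno, scale = scaled)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty genotype matrix",
                                           call. = FALSE)
  stopifnot(length(y) == nrow(X))
  y <- y - mean(y)
  D <- colSums(X^2)
  n <- length(y)
  scales <- resolve_prior_scales(cfg, mix, sum(D), n, sum(y^2) / n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- bayesr_mcmc_cpp(
    X = X, y = y,
    gamma = mix$gamma, pi_init = mix$pi_init,
    dirichlet_alpha = mix$dirichlet_alpha,
    nu_beta = cfg$nu_beta, S2_beta = scales$S2_beta,
    nu_eps = cfg$nu_eps, S2_eps = scales$S2_eps,
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
    permute = identical(cfg$update_order, "permuted"),
    resid_check_every = cfg$rhs_check_every)
  finish_posterior(res, mix, geno$info$snp_id, geno$freq, scaled)
}
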