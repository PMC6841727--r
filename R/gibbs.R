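#' Mixture prior specification
#'
#' The SNP-effect prior is a finite mixture: a point mass at zero
#' (component 1) plus `C - 1` normals `N(0, gamma_c * sigma_beta^2)`.
#' The default four-component weights `gamma = (0, 0.01, 0.1, 1)` express the
#' variance classes relative to a common `sigma_beta^2` that is itself
#' sampled, so the model applies to centred or scaled genotypes alike.
#'
#' @param gamma Non-decreasing variance weights; `gamma[1]` must be 0 and
#'   `gamma[C] > 0`.
#' @param pi_init Initial mixing proportions, summing to 1.
#' @param dirichlet_alpha Dirichlet prior pseudo-counts for `pi` (scalar or
#'   length-C vector). Default 1 per component.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(gamma = c(0, 0.01, 0.1, 1.0),
                         pi_init = c(0.95, 0.02, 0.02, 0.01),
                         dirichlet_alpha = 1) {
  C <- length(gamma)
  stopifnot(C >= 2L, gamma[1] == 0, gamma[C] > 0, !is.unsorted(gamma),
            length(pi_init) == C, all(pi_init > 0))
  if (abs(sum(pi_init) - 1) > 1e-8) stop("pi_init must sum to 1",
                                         call. = FALSE)
  if (length(dirichlet_alpha) == 1L) {
    dirichlet_alpha <- rep(dirichlet_alpha, C)
  }
  stopifnot(length(dirichlet_alpha) == C, all(dirichlet_alpha > 0))
  structure(list(C = C, gamma = as.numeric(gamma),
                 pi_init = as.numeric(pi_init / sum(pi_init)),
                 dirichlet_alpha = as.numeric(dirichlet_alpha)),
            class = "mixture_spec")
}

#' MCMC chain configuration
#'
#' Defaults follow the standard protocol for this model family: 10,000
#' iterations, 4,000 burn-in, thinning 1 in 10 (600 retained samples).
#' `S2_beta_init = NULL` resolves at run time so that the implied genetic
#' variance under `pi_init` equals half the phenotypic variance;
#' `S2_eps_init = NULL` resolves to the phenotypic variance. Both scaled
#' inverse-chi-squared priors use 4 degrees of freedom by default.
#'
#' @param n_iter,burn_in,thin Chain length, burn-in, thinning interval.
#' @param seed Optional integer seed applied via `set.seed()` before sampling.
#' @param nu_beta,S2_beta_init Prior df and scale for `sigma_beta^2`.
#' @param nu_eps,S2_eps_init Prior df and scale for `sigma_eps^2`.
#' @param update_order `"fixed"` (genomic order; required for the
#'   individual-level equivalence check) or `"permuted"` (fresh random
#'   permutation each iteration).
#' @param rhs_check_every If positive, every this many iterations the
#'   incrementally maintained right-hand side `r*` is recomputed from scratch
#'   and the maximum relative deviation recorded (diagnostic, costs O(p *
#'   window)).
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 10000L, burn_in = 4000L, thin = 10L,
                         seed = NULL, nu_beta = 4, S2_beta_init = NULL,
                         nu_eps = 4, S2_eps_init = NULL,
                         update_order = c("fixed", "permuted"),
                         rhs_check_every = 0L) {
  update_order <- match.arg(update_order)
  stopifnot(burn_in < n_iter, thin >= 1L, nu_beta > 0, nu_eps > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 nu_beta = nu_beta, S2_beta_init = S2_beta_init,
                 nu_eps = nu_eps, S2_eps_init = S2_eps_init,
                 update_order = update_order,
                 rhs_check_every = as.integer(rhs_check_every)),
            class = "chain_config")
}

# Resolve the data-dependent prior scales. var_y is the phenotypic variance
# (y'y / n_bar); sum_d = sum of D_jj. The implied genetic variance of the
# prior is sigma_beta^2 * E[gamma] * sum(D_jj) / n_bar with
# E[gamma] = sum(pi_init * gamma); the default scale sets that to var_y / 2.
resolve_prior_scales <- function(cfg, mix, sum_d, n_bar, var_y) {
  s2b <- cfg$S2_beta_init
  if (is.null(s2b)) {
    mean_gamma <- sum(mix$pi_init * mix$gamma)
    s2b <- 0.5 * var_y / (mean_gamma * sum_d / n_bar)
  }
  s2e <- cfg$S2_eps_init
  if (is.null(s2e)) s2e <- var_y
  # tiny positive floors keep degenerate (zero-variance) inputs well defined;
  # the effect-variance floor is far below the residual floor so a null
  # phenotype yields h2 ~ 0 rather than a ratio of floors
  list(S2_beta = max(s2b, 1e-30), S2_eps = max(s2e, 1e-12))
}

#' Run the summary-statistics SBayesR Gibbs sampler
#'
#' Samples SNP effects `beta`, component labels, mixing proportions `pi`,
#' `sigma_beta^2` and `sigma_eps^2` from their full conditionals given the
#' reconstructed sufficient statistics and a sparse shrunk LD reference,
#' recording the SNP-based heritability `h2 = sigma_g^2 / (sigma_g^2 +
#' sigma_eps^2)` at every iteration, with `sigma_g^2 = beta' X'X beta /
#' n_bar`. Per iteration the sampler sweeps every SNP (right-hand-side
#' updating over the SNP's LD window), then updates `sigma_beta^2`, `pi`
#' and `sigma_eps^2`.
#'
#' @param stats A `sufficient_stats` (see [reconstruct_sufficient()]); SNP
#'   list and order must match `ld`.
#' @param ld A `sparse_ld` over the same SNPs in the same order.
#' @param mix A [mixture_spec()].
#' @param cfg A [chain_config()].
#' @return A list of class `posterior_summary`: posterior means
#'   (`beta_mean` on the model scale, `beta_mean_allele` on the per-allele
#'   scale, `pip`, `comp_prob`, `h2_mean`, `h2_ci`, `pi_mean`), thinned
#'   traces (`h2_samples`, `pi_samples`, `sigma2_samples`, `beta_samples`)
#'   and diagnostics (`rhs_max_rel_err` when requested).
#' @export
run_sbayesr <- function(stats, ld, mix = mixture_spec(), cfg = chain_config()) {
  stopifnot(inherits(stats, "sufficient_stats"), inherits(ld, "sparse_ld"))
  p <- length(stats$D_diag)
  if (nrow(ld$info) != p || !identical(as.character(ld$info$snp_id),
                                       as.character(stats$snp_id))) {
    stop("stats and LD reference must cover identical SNPs in identical order",
         call. = FALSE)
  }
  scales <- resolve_prior_scales(cfg, mix, sum(stats$D_diag), stats$n_bar,
                                 stats$yty / stats$n_bar)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- sbayesr_mcmc_cpp(
    D_diag = stats$D_diag, Xty = stats$Xty, yty = stats$yty,
    n_bar = stats$n_bar,
    window_start = ld$info$window_start, values = ld$values,
    gamma = mix$gamma, pi_init = mix$pi_init,
    dirichlet_alpha = mix$dirichlet_alpha,
    nu_beta = cfg$nu_beta, S2_beta = scales$S2_beta,
    nu_eps = cfg$nu_eps, S2_eps = scales$S2_eps,
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
    permute = identical(cfg$update_order, "permuted"),
    rhs_check_every = cfg$rhs_check_every)
  finish_posterior(res, mix, stats$snp_id, stats$freq, stats$scaled)
}

# Common posterior summarisation for both samplers.
finish_posterior <- function(res, mix, snp_id, freq, scaled) {
  beta_mean <- rowMeans(res$beta_samples)
  pip <- rowMeans(res$comp_samples > 1L)
  comp_prob <- t(apply(res$comp_samples, 1L, function(z) {
    tabulate(z, nbins = mix$C) / length(z)
  }))
  beta_allele <- beta_mean
  if (isTRUE(scaled) && !is.null(freq)) {
    beta_allele <- beta_mean / sqrt(2 * freq * (1 - freq))
  }
  h2 <- res$h2_samples
  structure(list(
    snp_id = snp_id,
    beta_mean = beta_mean,
    beta_mean_allele = beta_allele,
    pip = pip,
    comp_prob = comp_prob,
    h2_samples = h2,
    h2_mean = mean(h2),
    h2_ci = stats::quantile(h2, c(0.025, 0.975), names = FALSE),
    pi_samples = res$pi_samples,
    pi_mean = rowMeans(res$pi_samples),
    sigma2_samples = res$sigma2_samples,
    beta_samples = res$beta_samples,
    rhs_max_rel_err = res$rhs_max_rel_err,
    n_nonzero_mean = mean(colSums(res$comp_samples > 1L))
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary over", length(x$h2_samples), "thinned samples\n")
  cat("  h2_SNP: mean", round(x$h2_mean, 4), " 95% CI [",
      round(x$h2_ci[1], 4), ",", round(x$h2_ci[2], 4), "]\n")
  cat("  pi:", paste(round(x$pi_mean, 4), collapse = " "), "\n")
  cat("  mean nonzero SNPs per sample:", round(x$n_nonzero_mean, 1), "\n")
  invisible(x)
}

#' Write posterior SNP effects and parameter trace to text files
#'
#' `prefix.snpRes`: SNP id, counted allele, posterior-mean effect (per-allele
#' scale), PIP and per-component probabilities. `prefix.parRes`: thinned trace
#' of `sigma_beta^2`, `sigma_eps^2`, `h2` and `pi`.
#'
#' @param post A `posterior_summary`.
#' @param prefix Output prefix.
#' @param A1 Optional counted-allele vector (defaults to `"A1"` placeholder).
#' @return `prefix`, invisibly.
#' @export
write_posterior <- function(post, prefix, A1 = NULL) {
  C <- ncol(post$comp_prob)
  snp <- data.frame(SNP = post$snp_id,
                    A1 = if (is.null(A1)) "A1" else A1,
                    beta = post$beta_mean_allele,
                    PIP = post$pip)
  for (c in seq_len(C)) snp[[paste0("comp", c)]] <- post$comp_prob[, c]
  utils::write.table(snp, paste0(prefix, ".snpRes"), quote = FALSE,
                     row.names = FALSE)
  par <- data.frame(sample = seq_along(post$h2_samples),
                    sigma2_beta = post$sigma2_samples[1L, ],
                    sigma2_eps = post$sigma2_samples[2L, ],
                    h2 = post$h2_samples,
                    t(post$pi_samples))
  names(par)[-(1:4)] <- paste0("pi", seq_len(C))
  utils::write.table(par, paste0(prefix, ".parRes"), quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

# ---- Single-step reference operations -------------------------------------
# R-level implementations of the individual Gibbs updates. These document the
# algorithm and are unit-tested against closed forms; the full chain runs in
# the compiled core, which is itself verified against the independently coded
# individual-level sampler.

#' Initialise a Gibbs state
#'
#' @param stats A `sufficient_stats`.
#' @param mix A [mixture_spec()].
#' @param cfg A [chain_config()].
#' @return A list of class `gibbs_state` with elements `beta, comp, pi,
#'   sigma2_beta, sigma2_eps, r_star` (`r_star = X'y` at `beta = 0`).
#' @export
gibbs_state_init <- function(stats, mix = mixture_spec(),
                             cfg = chain_config()) {
  p <- length(stats$D_diag)
  scales <- resolve_prior_scales(cfg, mix, sum(stats$D_diag), stats$n_bar,
                                 stats$yty / stats$n_bar)
  structure(list(beta = numeric(p), comp = rep(1L, p), pi = mix$pi_init,
                 sigma2_beta = scales$S2_beta, sigma2_eps = scales$S2_eps,
                 r_star = stats$Xty,
                 S2_beta = scales$S2_beta, S2_eps = scales$S2_eps),
            class = "gibbs_state")
}

#' Gibbs update of one SNP effect
#'
#' Computes `r_j = r*_j + (X'X)_jj beta_j`, evaluates the per-component
#' log marginal likelihoods
#' `log L_c = log pi_c + (1/2) [ log(s2e / (s2e + g_c s2b d_j)) +
#' r_j^2 g_c s2b / (s2e (s2e + g_c s2b d_j)) ]` (`log L_1 = log pi_1`),
#' draws the component label, then draws
#' `beta_j ~ N(r_j / l_jc, s2e / l_jc)` with
#' `l_jc = d_j + s2e / (g_c s2b)` (zero for component 1), and subtracts
#' `(X'x_j) * (beta_new - beta_old)` from `r*` over the SNP's LD window.
#'
#' @param j SNP index.
#' @param state A `gibbs_state`.
#' @param stats A `sufficient_stats`.
#' @param ld A `sparse_ld`.
#' @param mix A [mixture_spec()].
#' @param force_comp Optional fixed component label (bypasses the categorical
#'   draw; used for closed-form checks).
#' @return The updated `gibbs_state`.
#' @export
sweep_snp <- function(j, state, stats, ld, mix = mixture_spec(),
                      force_comp = NULL) {
  d_j <- stats$D_diag[j]
  s2e <- state$sigma2_eps
  s2b <- state$sigma2_beta
  r_j <- state$r_star[j] + d_j * state$beta[j]
  logL <- log(state$pi)
  for (c in 2:mix$C) {
    gs <- mix$gamma[c] * s2b
    logL[c] <- logL[c] + 0.5 * (log(s2e / (s2e + gs * d_j)) +
                                  r_j^2 * gs / (s2e * (s2e + gs * d_j)))
  }
  if (is.null(force_comp)) {
    pr <- exp(logL - max(logL))
    pr <- pr / sum(pr)
    comp <- sample_categorical(pr)
  } else {
    comp <- as.integer(force_comp)
  }
  beta_old <- state$beta[j]
  if (comp == 1L) {
    beta_new <- 0
  } else {
    l_jc <- d_j + s2e / (mix$gamma[comp] * s2b)
    beta_new <- stats::rnorm(1L, mean = r_j / l_jc, sd = sqrt(s2e / l_jc))
  }
  state$comp[j] <- comp
  state$beta[j] <- beta_new
  delta <- beta_new - beta_old
  if (delta != 0) {
    idx <- ld$info$window_start[j]:ld$info$window_end[j]
    xtxj <- sqrt(stats$D_diag[idx]) * ld$values[[j]] * sqrt(d_j)
    state$r_star[idx] <- state$r_star[idx] - xtxj * delta
  }
  state
}

# Inverse-CDF categorical draw from one uniform (same scheme as the compiled
# cores, so seeded streams line up).
sample_categorical <- function(pr) {
  u <- stats::runif(1L)
  cum <- cumsum(pr)
  comp <- which(u <= cum)[1L]
  if (is.na(comp)) comp <- length(pr)
  comp
}

#' Gibbs update of the common effect-variance parameter
#'
#' Draws `sigma_beta^2` from its scaled inverse-chi-squared full conditional
#' with df `nu_beta + q` and scale
#' `(sum_{j in model} beta_j^2 / gamma_{c_j} + nu_beta S2_beta) /
#' (nu_beta + q)`, `q` the number of SNPs in nonzero components.
#'
#' @param state A `gibbs_state`.
#' @param mix A [mixture_spec()].
#' @param nu_beta,S2_beta Prior df and scale.
#' @return Positive scalar draw.
#' @export
sample_sigma2_beta <- function(state, mix = mixture_spec(), nu_beta = 4,
                               S2_beta = state$S2_beta) {
  nz <- state$comp > 1L
  q <- sum(nz)
  ssq <- if (q > 0L) sum(state$beta[nz]^2 / mix$gamma[state$comp[nz]]) else 0
  df <- nu_beta + q
  scale <- (ssq + nu_beta * S2_beta) / df
  df * scale / stats::rchisq(1L, df)
}

#' Gibbs update of the residual variance
#'
#' Computes `SSE = y'y - beta' (X'y + r*)` (the summary-data identity for
#' `y'y - 2 beta' X'y + beta' X'X beta`), floors it at a small positive value,
#' and draws from a scaled inverse-chi-squared with df `nu_eps + n_bar` and
#' scale `(SSE + nu_eps S2_eps) / (nu_eps + n_bar)`.
#'
#' @param state A `gibbs_state`.
#' @param stats A `sufficient_stats`.
#' @param nu_eps,S2_eps Prior df and scale.
#' @return Positive scalar draw.
#' @export
sample_sigma2_eps <- function(state, stats, nu_eps = 4,
                              S2_eps = state$S2_eps) {
  sse <- stats$yty - sum(state$beta * (stats$Xty + state$r_star))
  if (!is.finite(sse)) {
    stop("divergence: non-finite residual sum of squares; check summary-",
         "statistic consistency (QC on n, alleles, frequencies)",
         call. = FALSE)
  }
  sse <- max(sse, 1e-12 * stats$yty)
  df <- nu_eps + stats$n_bar
  scale <- (sse + nu_eps * S2_eps) / df
  df * scale / stats::rchisq(1L, df)
}

#' Gibbs update of the mixing proportions
#'
#' Dirichlet draw with parameters `dirichlet_alpha + per-component counts`.
#'
#' @param state A `gibbs_state`.
#' @param mix A [mixture_spec()].
#' @return Probability vector of length `C`.
#' @export
sample_pi <- function(state, mix = mixture_spec()) {
  counts <- tabulate(state$comp, nbins = mix$C)
  g <- stats::rgamma(mix$C, shape = mix$dirichlet_alpha + counts, rate = 1)
  g / sum(g)
}

#' SNP-based heritability of the current state
#'
#' `sigma_g^2 = beta' (X'y - r*) / n_bar` (equal to the variance of the
#' genetic values `X beta` for centred genotypes, denominator `n`), and
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_eps^2)`.
#'
#' @param state A `gibbs_state`.
#' @param stats A `sufficient_stats`.
#' @return Scalar in `[0, 1)` for consistent inputs.
#' @export
compute_h2 <- function(state, stats) {
  sigma_g2 <- sum(state$beta * (stats$Xty - state$r_star)) / stats$n_bar
  sigma_g2 / (sigma_g2 + state$sigma2_eps)
}
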