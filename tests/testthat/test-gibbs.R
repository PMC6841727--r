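# Single-site conditional with all other effects zero: one SNP, exact
# sufficient statistics chosen by hand.
one_snp_state <- function(d = 100, b = 0.2, s2e = 1, s2b = 0.01,
                          yty = 100, n_bar = 100) {
  stats <- structure(list(snp_id = "s1", D_diag = d, Xty = d * b, yty = yty,
                          n_bar = n_bar, scaled = FALSE, freq = 0.3),
                     class = "sufficient_stats")
  ld <- structure(list(info = data.frame(snp_id = "s1", window_start = 1L,
                                         window_end = 1L, nnz = 1L),
                       values = list(1)),
                  class = "sparse_ld")
  mix <- mixture_spec(gamma = c(0, 1), pi_init = c(0.5, 0.5))
  st <- gibbs_state_init(stats, mix, chain_config(S2_beta_init = s2b,
                                                  S2_eps_init = s2e))
  list(stats = stats, ld = ld, mix = mix, state = st)
}

test_that("sweep_snp draws from the closed-form conditional", {
  # d = n = 100, b = 0.2 so r_j = X'y_j = 20; gamma = 1, s2e/s2b = 100
  # -> l_j = 100 + 100 = 200, conditional mean 20/200 = 0.1
  fx <- one_snp_state()
  set.seed(1)
  draws <- replicate(8000, {
    sweep_snp(1, fx$state, fx$stats, fx$ld, fx$mix, force_comp = 2)$beta[1]
  })
  expect_lt(abs(mean(draws) - 0.1), 4 * sd(draws) / sqrt(8000))
  expect_lt(abs(var(draws) - 1 / 200), 4 * (1 / 200) * sqrt(2 / 8000))

  # null component leaves beta 0 and r_star untouched
  st0 <- sweep_snp(1, fx$state, fx$stats, fx$ld, fx$mix, force_comp = 1)
  expect_equal(st0$beta[1], 0)
  expect_equal(st0$r_star, fx$state$r_star)

  # vanishing ridge: as gamma * s2b -> Inf the mean approaches r_j / d_j
  fx2 <- one_snp_state(s2b = 1e8)
  set.seed(2)
  d2 <- replicate(2000, {
    sweep_snp(1, fx2$state, fx2$stats, fx2$ld, fx2$mix, force_comp = 2)$beta[1]
  })
  expect_lt(abs(mean(d2) - 0.2), 4 * sd(d2) / sqrt(2000))
})

test_that("sweep_snp maintains r_star over the LD window", {
  st <- tiny_study(n = 300, p = 30, seed = 77)
  stats <- exact_sufficient_stats(st$geno, st$y)
  ld <- full_ld(st$geno)
  mix <- mixture_spec()
  state <- gibbs_state_init(stats, mix, chain_config())
  set.seed(5)
  for (j in 1:30) state <- sweep_snp(j, state, stats, ld, mix)
  Xc <- centred_dosage(st$geno)
  XtX <- crossprod(Xc)
  r_exact <- stats$Xty - drop(XtX %*% state$beta)
  expect_equal(state$r_star, r_exact, tolerance = 1e-10)
})

test_that("sample_sigma2_beta follows the scaled inverse-chi-squared conditional", {
  mix <- mixture_spec()
  # q = 0: prior draw; scaled-inv-chi2(nu, S2) has mean nu*S2/(nu-2)
  state <- list(comp = rep(1L, 50), beta = numeric(50), S2_beta = 2)
  set.seed(3)
  d0 <- replicate(20000, sample_sigma2_beta(state, mix, nu_beta = 10,
                                            S2_beta = 2))
  expect_equal(mean(d0), 10 * 2 / (10 - 2), tolerance = 0.05)
  expect_true(all(d0 > 0))

  # large q with all beta_j^2 / gamma = v concentrates near v
  v <- 0.37
  q <- 5000
  state2 <- list(comp = rep(4L, q), beta = rep(sqrt(v), q), S2_beta = 1)
  set.seed(4)
  d1 <- replicate(500, sample_sigma2_beta(state2, mix, nu_beta = 4,
                                          S2_beta = 1))
  expect_equal(mean(d1), v, tolerance = 3 * sd(d1) / sqrt(500) + 0.01)
})

test_that("sample_sigma2_eps uses the summary-data SSE identity", {
  # beta = 0 -> SSE = y'y; check the draw's expectation
  stats <- structure(list(D_diag = rep(100, 5), Xty = rep(1, 5), yty = 100,
                          n_bar = 100), class = "sufficient_stats")
  state <- list(beta = numeric(5), r_star = rep(1, 5), S2_eps = 1)
  set.seed(6)
  d <- replicate(5000, sample_sigma2_eps(state, stats, nu_eps = 4, S2_eps = 1))
  df <- 4 + 100
  expect_equal(mean(d), df * ((100 + 4) / df) / (df - 2), tolerance = 0.02)

  # quadratic-form identity on a small dense instance:
  # beta'(X'y - r*) equals beta' X'X beta directly
  st <- tiny_study(n = 250, p = 20, seed = 13)
  stats2 <- exact_sufficient_stats(st$geno, st$y)
  Xc <- centred_dosage(st$geno)
  XtX <- crossprod(Xc)
  beta <- rnorm(20, 0, 0.05)
  r_star <- stats2$Xty - drop(XtX %*% beta)
  expect_equal(sum(beta * (stats2$Xty - r_star)),
               drop(t(beta) %*% XtX %*% beta), tolerance = 1e-8)
  # and SSE itself: y'y - beta'(X'y + r*) = |y - X beta|^2
  sse <- stats2$yty - sum(beta * (stats2$Xty + r_star))
  y <- st$y - mean(st$y)
  expect_equal(sse, sum((y - Xc %*% beta)^2), tolerance = 1e-8)
})

test_that("sample_pi draws a Dirichlet with count-updated parameters", {
  mix <- mixture_spec()
  # empty counts, alpha = 1: symmetric Dirichlet, expectation 1/4
  state0 <- list(comp = integer(0))
  set.seed(7)
  d0 <- replicate(8000, sample_pi(state0, mix))
  expect_equal(rowMeans(d0), rep(0.25, 4), tolerance = 0.02)
  expect_true(all(abs(colSums(d0) - 1) < 1e-12))

  # counts (990, 5, 4, 1) with alpha = 1 -> mean (991, 6, 5, 2) / 1004
  state1 <- list(comp = rep(1:4, c(990, 5, 4, 1)))
  set.seed(8)
  d1 <- replicate(8000, sample_pi(state1, mix))
  expect_equal(rowMeans(d1), c(991, 6, 5, 2) / 1004, tolerance = 0.01)
})

test_that("compute_h2 matches the explicit genetic-variance computation", {
  st <- tiny_study(n = 300, p = 25, seed = 19)
  stats <- exact_sufficient_stats(st$geno, st$y)
  Xc <- centred_dosage(st$geno)
  beta <- rnorm(25, 0, 0.05)
  XtX <- crossprod(Xc)
  state <- list(beta = beta, r_star = stats$Xty - drop(XtX %*% beta),
                sigma2_eps = 0.8)
  g <- drop(Xc %*% beta)
  sg2 <- sum(g^2) / length(g)    # centred X: mean(g) = 0 exactly
  expect_equal(compute_h2(state, stats), sg2 / (sg2 + 0.8), tolerance = 1e-8)

  state0 <- list(beta = numeric(25), r_star = stats$Xty, sigma2_eps = 0.8)
  expect_equal(compute_h2(state0, stats), 0)
  # sigma_g2 == sigma_eps2 -> 0.5
  state1 <- list(beta = beta, r_star = stats$Xty - drop(XtX %*% beta),
                 sigma2_eps = sg2)
  expect_equal(compute_h2(state1, stats), 0.5, tolerance = 1e-12)
})

test_that("run_sbayesr is deterministic given a seed and near-null on null data", {
  ds <- summary_dataset(snp_id = paste0("s", 1:30), A1 = "A", A2 = "G",
                        freq = runif(30, 0.1, 0.5), b = 0, se = 0.02,
                        n = 2000)
  stats <- reconstruct_sufficient(ds)
  g <- simulate_genotypes(500, 30, block_size = 10, rho = 0.5, seed = 33)
  ld <- full_ld(g)
  ld$info$snp_id <- ds$snp_id
  cfg <- chain_config(n_iter = 600, burn_in = 200, thin = 5, seed = 99)
  p1 <- run_sbayesr(stats, ld, cfg = cfg)
  p2 <- run_sbayesr(stats, ld, cfg = cfg)
  expect_identical(p1$beta_samples, p2$beta_samples)   # bitwise
  expect_identical(p1$h2_samples, p2$h2_samples)
  expect_lt(p1$h2_mean, 0.05)                          # null data
  expect_lt(max(abs(p1$beta_mean)), 0.05)

  # permuted update order also runs and is deterministic
  cfgp <- chain_config(n_iter = 200, burn_in = 100, thin = 5, seed = 42,
                       update_order = "permuted")
  q1 <- run_sbayesr(stats, ld, cfg = cfgp)
  q2 <- run_sbayesr(stats, ld, cfg = cfgp)
  expect_identical(q1$h2_samples, q2$h2_samples)

  # mismatched SNP lists are refused
  stats_bad <- reconstruct_sufficient(ds[1:29, ])
  expect_error(run_sbayesr(stats_bad, ld, cfg = cfg), "identical")
})

test_that("mixture_spec and chain_config validate their invariants", {
  expect_error(mixture_spec(gamma = c(0.1, 1)))            # gamma[1] != 0
  expect_error(mixture_spec(gamma = c(0, 1, 0.5)))         # not non-decreasing
  expect_error(mixture_spec(pi_init = c(0.5, 0.2, 0.2, 0.2)))  # sum != 1
  expect_error(chain_config(n_iter = 100, burn_in = 100))  # burn_in < n_iter
  m <- mixture_spec()
  expect_equal(m$gamma, c(0, 0.01, 0.1, 1))
  expect_equal(sum(m$pi_init), 1)
})
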