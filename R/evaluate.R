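#' Polygenic risk scores from per-allele effects
#'
#' `score_i = sum_j count_ij(A1_j) * beta_j`, where the effect table's `A1`
#' is matched against the panel's counted allele: when they are swapped the
#' counted dosage is reversed (`2 - count`); mismatching allele pairs are
#' dropped with a warning. Missing genotypes contribute the expected dosage
#' `2 * freq_j * beta_j`.
#'
#' @param geno A [genotype_matrix()].
#' @param effects `data.frame` with columns `snp_id, A1, beta` (optionally
#'   `A2`).
#' @return Numeric score vector, one per individual.
#' @export
compute_prs <- function(geno, effects) {
  stopifnot(all(c("snp_id", "A1", "beta") %in% names(effects)))
  idx <- match(effects$snp_id, geno$info$snp_id)
  keep <- !is.na(idx)
  if (!all(keep)) {
    warning(sum(!keep), " effect SNP(s) absent from the panel", call. = FALSE)
  }
  eff <- effects[keep, , drop = FALSE]
  idx <- idx[keep]
  pa1 <- toupper(geno$info$A1[idx])
  pa2 <- toupper(geno$info$A2[idx])
  ea1 <- toupper(eff$A1)
  same <- ea1 == pa1
  swapped <- ea1 == pa2
  if (!is.null(eff$A2)) {
    same <- same & toupper(eff$A2) == pa2
    swapped <- swapped & toupper(eff$A2) == pa1
  }
  bad <- !same & !swapped
  if (any(bad)) {
    warning(sum(bad), " effect SNP(s) with mismatching alleles dropped",
            call. = FALSE)
    eff <- eff[!bad, , drop = FALSE]
    idx <- idx[!bad]
    same <- same[!bad]
    swapped <- swapped[!bad]
  }
  if (nrow(eff) == 0L) stop("no scorable SNPs", call. = FALSE)
  X <- geno$X[, idx, drop = FALSE]
  if (anyNA(X)) {
    exp_dose <- rep(2 * geno$freq[idx], each = nrow(X))
    X[is.na(X)] <- exp_dose[is.na(X)]
  }
  dose <- X
  if (any(swapped)) {
    dose[, swapped] <- 2 - dose[, swapped, drop = FALSE]
  }
  drop(dose %*% eff$beta)
}

#' Prediction R-squared and calibration slope
#'
#' The squared Pearson correlation between observed phenotype and PRS (the
#' R2 of the simple linear regression), plus the calibration slope from
#' regressing the phenotype on the PRS — unity indicates a correctly scaled
#' predictor.
#'
#' @param y Observed phenotype.
#' @param prs Polygenic score.
#' @return A list with `r2` and `slope`.
#' @export
prediction_r2 <- function(y, prs) {
  stopifnot(length(y) == length(prs))
  v <- stats::var(prs)
  if (v == 0) return(list(r2 = 0, slope = NA_real_))
  r <- stats::cor(y, prs)
  list(r2 = r^2, slope = stats::cov(y, prs) / v)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random case scores higher than a random control, with
#' ties counted one half. Computed from rank sums, so monotone transforms of
#' the score leave it unchanged.
#'
#' @param y_binary 0/1 status vector (1 = case).
#' @param prs Score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_binary, prs) {
  stopifnot(length(y_binary) == length(prs))
  y_binary <- as.integer(y_binary)
  n1 <- sum(y_binary == 1L)
  n0 <- sum(y_binary == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both cases and controls", call. = FALSE)
  r <- rank(prs, ties.method = "average")
  (sum(r[y_binary == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Observed-scale to liability-scale heritability
#'
#' The standard transformation for case-control data:
#' `h2_liab = h2_obs * K^2 (1-K)^2 / (z^2 P (1-P))`, where `K` is the
#' population prevalence, `P` the sample case proportion and `z` the standard
#' normal density at the liability threshold `qnorm(1 - K)`. For population
#' samples `P = K` and the multiplier reduces to `K(1-K)/z^2`; the full form
#' is kept so case-oversampled studies are handled too.
#'
#' @param h2_obs Observed-scale heritability.
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion; defaults to `K`.
#' @return Liability-scale heritability.
#' @export
liability_h2 <- function(h2_obs, K, P = K) {
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2_obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Nested-model comparison of two polygenic scores
#'
#' ANOVA F test of `y ~ prs_low` against `y ~ prs_low + prs_high`, with the
#' partial R2 of the added score
#' (`(RSS_null - RSS_alt) / RSS_null`).
#'
#' @param y Observed phenotype.
#' @param prs_low,prs_high Lower- and higher-ranked scores.
#' @return A list with `F`, `p` and `partial_r2`.
#' @export
compare_models <- function(y, prs_low, prs_high) {
  null_fit <- stats::lm(y ~ prs_low)
  alt_fit <- stats::lm(y ~ prs_low + prs_high)
  an <- stats::anova(null_fit, alt_fit)
  rss0 <- an$RSS[1L]
  rss1 <- an$RSS[2L]
  Fv <- an$F[2L]
  list(F = if (is.na(Fv)) 0 else Fv,
       p = an$`Pr(>F)`[2L],
       partial_r2 = (rss0 - rss1) / rss0)
}

#' One-row evaluation metrics table
#'
#' @param y Observed phenotype (0/1 when `binary`).
#' @param prs Score vector.
#' @param binary Treat as case-control? Default FALSE.
#' @param K Population prevalence (binary case), for the liability transform.
#' @return A one-row `data.frame` with `r2`, `slope`, and for binary traits
#'   `auc` and `h2_liab_multiplier`-ready fields.
#' @export
evaluate_prs <- function(y, prs, binary = FALSE, K = NULL) {
  m <- prediction_r2(y, prs)
  out <- data.frame(r2 = m$r2, slope = m$slope)
  if (binary) {
    out$auc <- auc(y, prs)
    if (!is.null(K)) {
      out$h2_liab_of_r2 <- liability_h2(m$r2, K, P = mean(y))
    }
  }
  out
}
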