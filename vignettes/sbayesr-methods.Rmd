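---
title: "SBayesR: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SBayesR: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the reconstruction of sufficient statistics
from GWAS summary data, the Gibbs sampler, the LD shrinkage estimator, the
synthetic-data generator, and — importantly — the numerical and design
choices that were genuinely open, with the reasoning behind each. It closes
with the known limitations, including a stability phenomenon that anyone
running this model class at small scale should understand.

## 1. Model

For a centred phenotype $\mathbf{y}$ ($n \times 1$) and allele counts
$\mathbf{X}$ ($n \times p$, centred, optionally scaled),

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \boldsymbol\varepsilon,
\qquad \varepsilon_i \sim N(0, \sigma^2_\varepsilon).$$

Multiplying by $\mathbf{D}^{-1}\mathbf{X}'$ with
$\mathbf{D} = \mathrm{diag}(\mathbf{x}_j'\mathbf{x}_j)$ links the joint
coefficients to the marginal (single-SNP) least-squares estimates
$\mathbf{b} = \mathbf{D}^{-1}\mathbf{X}'\mathbf{y}$:

$$\mathbf{b} = \mathbf{D}^{-1/2}\,\mathbf{B}\,\mathbf{D}^{1/2}
\boldsymbol\beta + \mathbf{D}^{-1}\mathbf{X}'\boldsymbol\varepsilon,$$

where $\mathbf{B}$ is the LD correlation matrix. Everything the sampler
needs is therefore $(\mathbf{b}, \widehat{\mathbf{D}},
\widehat{\mathbf{B}}, \mathbf{y}'\mathbf{y})$:

* $\widehat{D}_{jj} = 1/(\widehat{se}_j^2 + b_j^2/n_j)$ for centred
  genotypes (`reconstruct_D(scaled = FALSE)`), or $n_j$ under the
  scaled-genotype convention. On data generated by this package's own GWAS
  the centred reconstruction agrees with the true diagonal of
  $\mathbf{X}'\mathbf{X}$ to well under 1%.
* $\mathbf{X}'\mathbf{y} = \widehat{\mathbf{D}}\mathbf{b}$.
* $\mathbf{y}'\mathbf{y}$: the phenotype is assumed centred and
  variance-standardised, so $\mathbf{y}'\mathbf{y} = \bar n$, the median
  per-SNP sample size. This is a deliberate convention, not an estimate:
  published summary statistics give no direct access to the phenotypic
  sum of squares, and the standardised-trait assumption matches how
  phenotypes are prepared before GWAS in this field. When an in-sample
  panel is available, `exact_sufficient_stats()` supplies the exact scalar
  instead.

The prior on each effect is the BayesR mixture — a point mass at zero plus
$C - 1$ normals $N(0, \gamma_c\sigma^2_\beta)$ — with a Dirichlet prior on
the mixing proportions and scaled inverse-$\chi^2$ priors on both variance
components. The variance weights are expressed relative to a *sampled*
common $\sigma^2_\beta$ (default $\gamma = (0, 0.01, 0.1, 1)$), which
decouples the mixture from the number of SNPs and lets the same prior serve
centred or scaled genotypes.

## 2. Gibbs sampler and right-hand-side updating

Per iteration the sampler sweeps all SNPs in genomic order, then updates
$\sigma^2_\beta$, $\boldsymbol\pi$ and $\sigma^2_\varepsilon$, and records
$h^2_{\mathrm{SNP}}$. The per-SNP step (`sweep_snp()`) computes
$r_j = r^*_j + (\mathbf{X}'\mathbf{X})_{jj}\beta_j$ from the maintained
right-hand side $\mathbf{r}^* = \mathbf{X}'\mathbf{y} -
\mathbf{X}'\mathbf{X}\boldsymbol\beta$, evaluates the marginal likelihood
of $r_j$ under each mixture component (effect integrated out), draws the
component label, draws
$\beta_j \sim N(r_j/l_{jc},\, \sigma^2_\varepsilon/l_{jc})$ with
$l_{jc} = (\mathbf{X}'\mathbf{X})_{jj} +
\sigma^2_\varepsilon/(\gamma_c\sigma^2_\beta)$ for non-null components, and
subtracts $(\mathbf{X}'\mathbf{x}_j)(\beta_j^{new} - \beta_j^{old})$ from
$\mathbf{r}^*$ — touching only the SNP's sparse LD window. The compiled
core re-verifies this bookkeeping on demand (`rhs_check_every`): the
maintained $\mathbf{r}^*$ agrees with a from-scratch recomputation to
better than $10^{-8}$ throughout the test chains.

The residual-variance update uses the summary-data identity
$SSE = \mathbf{y}'\mathbf{y} - \boldsymbol\beta'(\mathbf{X}'\mathbf{y} +
\mathbf{r}^*)$, which equals $\|\mathbf{y} - \mathbf{X}\beta\|^2$ when the
LD matrix is exact. With an approximate LD matrix this quantity can go
negative; it is floored at $10^{-12}\,\mathbf{y}'\mathbf{y}$ (see §7).

$h^2_{\mathrm{SNP}}$ is computed every iteration as
$\sigma^2_g/(\sigma^2_g + \sigma^2_\varepsilon)$ with $\sigma^2_g =
\boldsymbol\beta'(\mathbf{X}'\mathbf{y} - \mathbf{r}^*)/\bar n =
\boldsymbol\beta'\mathbf{X}'\mathbf{X}\boldsymbol\beta/\bar n$. The
denominator is $n$, not $n-1$: with centred genotypes the mean of
$\mathbf{X}\beta$ is exactly zero, and this convention makes the
summary-data expression algebraically identical to the individual-level
one, which the equivalence check below requires.

## 3. The individual-level oracle

`run_bayesr()` is the same hierarchical model coded independently against
individual data: it maintains the residual vector $\mathbf{e} = \mathbf{y} -
\mathbf{X}\boldsymbol\beta$ on individuals and computes
$r_j = \mathbf{x}_j'\mathbf{e} + \mathbf{x}_j'\mathbf{x}_j\beta_j$ by dense
dot products. The two samplers share no implementation — only the RNG call
pattern (one uniform per label, one normal per non-null effect, then the
$\chi^2$ and Gamma draws in fixed order) is common, so that with the same
seed and fixed update order they can be compared draw for draw. With
$\widehat{\mathbf{D}}$ and $\widehat{\mathbf{B}}$ computed exactly from the
GWAS panel (no shrinkage, no cutoff) the two are algebraically equivalent;
the acceptance suite verifies the thinned draws agree to $10^{-6}$
relative (in practice $\sim 10^{-14}$) at $n = 500$, $p = 200$ over 2,000
iterations. This equivalence is the package's primary correctness anchor:
it validates the likelihood, all four conditional updates and the
right-hand-side algebra in one shot.

## 4. LD reference construction

`build_sparse_ld()` computes pairwise Pearson correlations on a reference
panel (missing genotypes mean-imputed per SNP, correlations on centred
columns — identical to Pearson) and multiplies each off-diagonal by the
shrinkage factor $\exp(-\varrho_{ij}/2m)$, $\varrho_{ij} = 4 N_e c_{ij}$.

**Units.** $c_{ij}$ enters in **Morgans** (cM/100), the Li–Stephens/
Wen–Stephens convention. With $N_e = 11{,}400$ and $m = 183$ the factor
reaches the $10^{-3}$ cutoff at $c \approx 0.0554$ Morgans ($\approx$
5.5 cM $\approx$ 5.5 Mb at 1 cM/Mb) — reproducing the $\sim$10 Mb windows
this estimator is known for. Read literally in centimorgans the factor
would zero essentially every entry, so the Morgan reading is the only one
consistent with the method's published window widths; it is fixed here and
stated prominently because the two conventions differ by a factor of 100.

Because genetic position is monotone in genomic order, each SNP's retained
neighbours form one contiguous index range. Windows are stored as these
ranges (including any interior zeros), which is what makes the sampler's
update a single short vector operation. No positive-semidefinite repair is
applied after thresholding; the sampler does not require PSD input, and the
consequences of the resulting inconsistency are discussed in §7.

Defaults $N_e = 11{,}400$, $m = 183$, cutoff $10^{-3}$ follow the
established choices for European-ancestry panels with the interpolated
1000G CEU map.

## 5. The synthetic-data generator

`simulate_genotypes()` draws per-SNP MAFs uniformly (default 0.05–0.5) and
builds two latent Gaussian-copula AR(1) haplotypes per block, thresholded
at the MAF quantile and summed to 0/1/2 counts. This gives controllable,
blocky LD with independent blocks — the structure the method's windowed LD
reference assumes — at desk scale and with exact reproducibility, which a
coalescent simulator would not provide as directly.

Geometry was a genuinely open choice and it matters. Positions are laid
out contiguously at 3 kb spacing (HapMap3-like density, $\sim$300 SNPs/Mb);
blocks of 100 SNPs then span $\sim$300 kb, a realistic LD-block scale, and
the 5.5 cM shrinkage window covers thousands of SNPs, as it does at genome
scale. An earlier layout that separated blocks by 10 Mb gaps produced
windows of only $\sim$100 SNPs — 36-fold smaller in SNP count than the
real-data windows — and grossly over-weighted LD truncation relative to the
regime the method was designed for. A desk-scale panel of $p = 2{,}000$
SNPs is necessarily smaller than one real-data window, a distortion to keep
in mind when reading the simulation studies (§7).

The architecture generator mirrors the standard designs: the
BayesR-mixture mode draws stated numbers of causal variants from
$N(0, 0.01\sigma^2_\beta)$, $N(0, 0.1\sigma^2_\beta)$ and
$N(0, \sigma^2_\beta)$ — 2,500/5,000/2,500 at full genome scale; the
scaled-down studies use 50/100/50 of $p = 2{,}000$, preserving the 1:2:1
ratio. Phenotypes are built on centred-and-scaled genotypes with the
residual variance set to $\mathrm{var}(g)(1-h^2)/h^2$, so the realised
heritability matches the target by construction. Case–control status is
the liability threshold rule: case iff the standardised liability exceeds
$\Phi^{-1}(1-K)$; the default scenario prevalence is $K = 0.05$.

What the generator does **not** emulate: relatedness, population
stratification, imputation error, allele-coding errors, per-SNP sample-size
heterogeneity, and long-range or inter-chromosomal LD. Passing tests on
this generator therefore demonstrate the estimator's internal correctness
and its behaviour under clean, well-specified inputs — not robustness to
the artefacts real summary statistics carry (the QC module exists precisely
because real inputs are not clean).

## 6. Defaults and tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| $\gamma$ | $(0, 0.01, 0.1, 1)$ | mixture variance weights, relative to $\sigma^2_\beta$ |
| $\pi$ (initial) | $(0.95, 0.02, 0.02, 0.01)$ | starting mixing proportions |
| Dirichlet $\alpha$ | 1 per component | prior pseudo-counts for $\pi$ |
| $\nu_\beta$, $\nu_\varepsilon$ | 4, 4 | prior degrees of freedom |
| $S^2_\beta$ (initial) | implied genetic variance = half the phenotypic variance under $\pi_{init}$ | resolved from the data at run time |
| $S^2_\varepsilon$ (initial) | phenotypic variance $\mathbf{y}'\mathbf{y}/\bar n$ | resolved at run time |
| chain | 10,000 iterations, 4,000 burn-in, thin 10 | 600 retained samples |
| $N_e$, $m$, cutoff | 11,400, 183, $10^{-3}$ | shrinkage estimator |
| QC | MAF > 0.01; drop A/T, C/G; $n$ within [2.5, 95] percentiles | summary-statistic filters |

The update order is fixed genomic order by default (a seeded permutation is
available); fixed order is required for the draw-for-draw oracle
comparison. The parameter-recovery studies in the test suite use shorter
chains (3,000–5,000 iterations) than the 10,000-iteration default; at these
problem sizes ($p \le 2{,}000$) the chains mix quickly and posterior means
are stable well before that, which the recovery results themselves confirm.

## 7. Numerical choices, degenerate inputs and the stability limitation

**Floors.** The data-resolved prior scales are floored
($S^2_\beta \ge 10^{-30}$, $S^2_\varepsilon \ge 10^{-12}$) so a
zero-variance phenotype yields $h^2 \approx 0$ rather than a ratio of
floors; $SSE$ is floored at $10^{-12}\mathbf{y}'\mathbf{y}$. Exact-fit
GWAS regressions floor the standard error at the smallest positive double
to preserve the $se > 0$ invariant; p-values are floored at the smallest
positive double to stay in $(0, 1]$.

**Categorical draws** use a single uniform against the cumulative
component probabilities (identically coded in both samplers), and
**divergence guards** abort with an actionable message if a sampled state
becomes non-finite — the model's known response to inconsistent summary
data, and the reason the QC filters exist.

**Percentile QC** uses R's linear-interpolation quantile (type 7) with
strict exclusion outside the band. A strict percentile rule on distinct
values is not idempotent (re-application trims further); on realistic
summary sets, where the per-SNP $n$ is near-constant with outliers, the
rule removes the outliers once and is then stable, which is the regime the
idempotence test exercises. The post-alignment allele-frequency discrepancy
threshold is 0.2 — wide enough to pass sampling noise at any realistic
panel size, tight enough to catch strand and coding errors.

**The stability limitation.** The residual-variance update ties
$\sigma^2_\varepsilon$ to a quadratic form whose
$\boldsymbol\beta'\mathbf{X}'\mathbf{X}\boldsymbol\beta$ term uses the
*approximate* LD matrix while $\mathbf{X}'\mathbf{y}$ embeds the GWAS
panel's *exact* sample LD. Any mismatch — shrinkage, window truncation, or
reference-panel sampling noise — leaves a component of the marginal signal
that the model cannot attribute to LD and instead absorbs as many small
effects, deflating $SSE$, which sharpens the component likelihoods, which
recruits more effects. At biobank scale this feedback is weak and the
estimator's upward $h^2$ bias stays small; the package's scaled-down bias
study (3,000 GWAS individuals, a 1,000-individual reference, $p = 2{,}000$)
shows the other side of the same phenomenon: for $h^2 \ge 0.2$ the chain
escapes to $h^2 \to 1$ within a few sweeps, and the measured bias is large.
The effect is not an implementation artefact — the identical sampler under
exact in-sample LD recovers the generating $h^2$ to within Monte-Carlo
error (§3, and the recovery study at $n = 5{,}000$) — and it reproduces the
documented sensitivity of this model class to LD-reference inconsistency,
which at full scale is managed with large references (tens of thousands of
individuals) and strict summary-statistic QC. Users applying this package
to small panels should treat a posterior $h^2$ near 1, or a
number-of-nonzero-effects count near $p$, as a divergence signature, and
prefer the largest and most in-sample-like LD reference available.

**Problem sizes.** The shipped studies use $n$ up to 6,000 and $p \le
2{,}000$ with 2,000–5,000 MCMC iterations — sizes chosen so the full
validation suite runs on a laptop while still separating the stable and
unstable regimes described above.

## 8. Other known limitations

* Summary statistics from linear mixed models violate the least-squares
  assumption behind the $\widehat{\mathbf{D}}$ reconstruction; no
  effective-sample-size correction is implemented, and such inputs should
  be treated with caution.
* No annotation-stratified priors and no multi-trait extension.
* The LD builder takes hard-call genotypes only; dosages are not supported.
* Case–control analyses are run on the observed 0/1 scale and transformed
  afterwards (`liability_h2()`); heavily case-oversampled designs deserve
  the usual caution about liability-scale interpretation.
* No liftover or rsID/position reconciliation: alignment is by SNP id.
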