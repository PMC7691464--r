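---
title: "Measuring contemporary selection in a mixed oak stand: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contemporary selection in a mixed oak stand: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakqg)
```

## The question and the estimation chain

`oakqg` implements an in-situ quantitative-genetic analysis of contemporary
selection for a mapped forest stand of two interfertile white oaks
(*Quercus petraea*, *Q. robur*) observed over two generations: a mature
adult cohort (G1) and the naturally regenerated sapling cohort (G2) it
produced. The pipeline asks three questions in sequence:

1. **Is there genetic variation in fitness?** Fitness of an adult is its
   reproductive success (RS): its contribution of surviving saplings as
   female or male parent, `RS = (RS_female + RS_male) / 2`, scaled to
   relative fitness `w = RS / mean(RS)` within species. The variance of
   `w` is the opportunity for selection *I*; its additive component comes
   from a univariate animal model.
2. **Which traits are under phenotypic selection?** Lande–Arnold
   univariate gradients per trait and species,

   `w = mu + C + E + P + beta * x_std (+ gamma * x_std^2) + e`

   where `x_std` is the SD-standardized trait, so `beta` is the selection
   intensity, and `C`, `E`, `P` absorb the stand's non-genetic structure:
   `C` the Hegyi competition index (`sum D_i / (D_j * Dist_ij)` within a
   closed 10 m ball), `E` the first principal component of five downscaled
   ecological variables, and `P` a single PCNM spatial eigenvector chosen
   by the AIC of its fitness regression.
3. **Is the trait–fitness association genetic?** The secondary theorem of
   selection: the expected genetic change of a trait equals its additive
   covariance with relative fitness, `Re = Cov(w_a, x_a)`, estimated by a
   bivariate REML animal model whose additive effect is structured by the
   VanRaden genomic relationship matrix
   `G = (M - P)(M - P)' / (2 * sum p_i (1 - p_i))` among adults. Predicted
   responses (`Re% = (G2_pred - G1) * 100 / G1`) are then confronted with
   two observed-response measures: the phenotypic difference between
   saplings of top-half and bottom-half parents (`Delta%`, median split of
   observed fitness per species) and the shift in mean breeding values
   across generations under a hybrid relatedness matrix (genomic among
   adults, pedigree-propagated to saplings). The comparison is
   deliberately restricted to *signs*: the pipeline reports concordance,
   not rates of change.

Because the study's raw data are not shipped, a synthetic stand generator
with full ground truth stands in for them, and every stage is validated by
parameter recovery plus the worked-example arithmetic of the published
response tables (shipped as a small text fixture).

## What the generator emulates — and what it does not

`simulate_stand()` reproduces the statistical structure the analysis
relies on: a ~5.2 ha plot (228 × 228 m) with mildly clustered adults;
lognormal female and male fecundities (unit mean, CV 1 by default) sharing
a heritable latent fitness (`h2_fitness = 0.6`, within the range implied
by published fitness-variance ratios); exponential seed and pollen kernels
(20 m and 60 m scales — acorn dispersal is short, pollen travels farther);
a sapling cohort sampled on a systematic grid jittered within a 3–6 m
spacing band; Mendelian transmission at a small (82 SNP) parentage panel
and a dense relatedness panel; multivariate-normal breeding values with a
single-factor covariance through fitness (so each trait's genetic
correlation with fitness is a direct input); and a smooth environment
built from ~10 Gaussian bumps with a 50 m length scale, feeding five
correlated ecological variables.

With `g1_founders > 0` the adults themselves descend from an unobserved
founder pool, giving the adult generation the sibship structure that real
stands inherit from earlier regeneration cycles. This matters: genomic
REML on a cohort of mutually unrelated founders has no relatedness
contrast to work with, and additive variances collapse to the boundary —
an authentic failure mode, and the reason the worked analyses use
`g1_founders = 25–30`.

The generator deliberately omits: overlapping generations, selfing,
linkage (loci are independent), hybridization between the species (mating
is within species, although both share the plot), mortality beyond
sampling, and pollen/seed immigration by default (an `immigration`
fraction exists but defaults to 0 because no rate is reported for the
study stand). Passing tests therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness to
every feature of real regeneration data.

## Estimation components and numerical choices

**Parentage.** A likelihood-based categorical assignment over all
unordered adult pairs (adults are monoecious, so every adult is a
candidate mother and father; selfing excluded). The error model mixes
Mendelian transmission with Hardy–Weinberg background at rate ε:
`P(g_o | g_m, g_f) = (1 - ε) P_mendel + ε P_HWE`. A pair is assigned when
its log-likelihood ratio against the "both parents unknown" HWE model is
positive and its count of strict opposing-homozygote exclusions is at most
5% of loci. The 3×3×3×loci lookup tables and the pair scan are compiled
code; 60 adults × 500 saplings × 82 SNPs takes ~2 s.

**Effective fecundities.** A fixed-kernel, spatially explicit mating
model: sapling *s* at site *y* arises from pair *(j, k)* with probability
proportional to `f_j K_s(d(j, y)) m_k K_p(d(j, k)) P_mendel(g_s | g_j,
g_k)`. Female (`f`) and male (`m`) fecundities are estimated by
expectation/conditional-maximization: given responsibilities, the
conditional M-steps for `f` (with `m` fixed) and `m` (with `f` fixed) are
exact closed forms, so the observed-data log-likelihood is non-decreasing
at every iteration — a property the tests assert verbatim. Kernels are
exponential with fixed scales supplied by the caller: kernel estimation is
the province of full Bayesian mating models and is out of scope here.
Convergence: absolute log-likelihood change < 1e-6, cap 500 iterations,
non-convergence flagged and warned, never silent.

**Relatedness.** VanRaden's first estimator with observed allele
frequencies by default (a `supplied` mode exists for recovery tests);
missing genotypes mean-imputed per locus (the recode `dosage - 2p` makes
the imputed entry exactly zero); monomorphic loci dropped with a message;
per-locus and per-individual missingness ceilings of 20%. The recoding
fixes the counted allele as the alternate allele; `G` is invariant to a
consistent flip. Pedigree relationships use the tabular recursion with
founders unrelated and non-inbred; the hybrid two-generation matrix runs
the same recursion with the adult genomic block as founder relatedness.
Matrices are conditioned by bending: if the smallest eigenvalue is below
1e-8 the deficit is added to the diagonal, leaving off-diagonals exact.

**PCNM.** Distances above the truncation threshold *t* are replaced by
4*t*, `-d^2/2` is Gower-centered and eigendecomposed, and positive-
eigenvalue axes are returned unit-norm. The pipeline default follows the
source analysis in setting *t* to the maximum pairwise distance, which
makes the truncation a no-op; for a planar configuration the matrix is
then Euclidean and exactly two positive axes exist (the classical
principal coordinates). That is sufficient for the single-covariate
selection rule used here; a smaller *t* yields the richer classical PCNM
basis and is fully supported (and used in tests, where axes beyond the
second carry planted signals). AIC for the per-axis fitness regression is
the Gaussian profile form `n log(RSS/n) + 2k` with `k = 3`; any consistent
convention gives the same argmin, which is all that is used. Ties resolve
to the lowest-ranked axis.

**REML.** The animal model is fitted by direct maximization of the
restricted log-likelihood. One eigendecomposition of the conditioned
relatedness matrix rotates the model so the covariance is block-diagonal
(t × t blocks `G0 d_i + R0`), making each likelihood evaluation O(n);
G0 and R0 are Cholesky-parameterized (log diagonals), optimized by
Nelder–Mead from three deterministic starts (additive shares 0.5, 0.2,
0.8 of the phenotypic covariance), polished by BFGS and a final simplex
pass at reltol 1e-15 — tight enough that the balanced half-sib fit matches
the closed-form ANOVA estimator to 1e-6. The reported log-likelihood
includes the `log |X'X|` term, so it is invariant to the fixed-effect
basis. Standard errors come from the numerically evaluated observed-
information matrix over the (co)variance parameterization at the optimum;
covariance significance uses the Wald criterion |estimate| > 1.96 SE,
matching the source's bold-if-significant presentation absent a stated
test. Boundary estimates (a variance below 1e-6 of phenotypic) are
flagged. BLUPs solve the mixed-model equations in the rotated space and
are checked against a dense solve.

**Scale transforms.** Fitness (and any non-Gaussian trait) is analysed
after a natural-log transform, then carried back to the data scale with
the exact lognormal closed forms `E[X] = exp(mu + s2/2)` and
`Cov[X, Y] = exp(mu_x + mu_y + (s2_x + s2_y)/2)(exp(s_xy) - 1)` — the
Gaussian-link integrals of general GLMM back-transformation, in closed
form. Relative fitness has mean 1 by construction, so the data-scale
covariance is approximately the log-scale covariance. Effective
fecundities are strictly positive, so `log(w)` needs no offset; realized
(count-based) fitness uses `delta = 1/(2 n_offspring)`.

## Conventions that were genuinely open

* **Opportunity for selection** uses the sample (n−1) variance of `w`,
  the standard convention in selection reporting.
* **Gradients on untransformed fitness.** The gradient model is written
  on `w` while the animal models use `log w`; published descriptions mix
  the two for gradients. Both modes are available (`log_fitness` flag);
  the default is untransformed, matching the linear model as written.
* **Quadratic gradients** report both the raw `x_std^2` coefficient and
  its doubled (Stinchcombe) value, since published tables rarely state
  which convention they use.
* **Parental-fitness split**: the adult at the species median goes to the
  bottom class; offspring whose two parents disagree are classed by the
  mean of the parental fitness values (alternatives `mother` and
  `exclude` are provided). Medians are species-specific because fitness
  is relative within species.
* **Negative-mean traits** (leaf δ13C, δ15N): percentage responses use
  the signed denominator, and a warning flags the sign ambiguity; the
  published tables are internally inconsistent for such cells, so the
  worked-example checks compare magnitudes there.
* **Parentage cannot orient a pair** (both sexes are possible for every
  adult), so each assignment credits half an offspring to each parent's
  female and male counts; effective fecundities estimate the two roles
  separately through the asymmetric seed/pollen kernels.

## Problem sizes used in validation

The recovery experiments are sized to finish comfortably on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances: 20
replicates of 400-sapling cohorts from 50 adults for heritability
(truth 0.2/0.5/0.8, mean estimate within ±0.1) and bivariate covariance
recovery (truth 0.3, mean within ±0.07); 1,000 null and 200 alternative
replicates at n = 200 for gradient calibration; a 200 × 5,000 HWE panel
for GRM sanity; 60 adults, 500 saplings and 82 SNPs (ε = 0.01, errors
injected and modelled) for parentage; 60 adults and 1,000 saplings for
fecundity recovery (Spearman vs truth, threshold 0.6 pinned from fixture
calibration). The analysis walk-through in `analysis/` uses a two-species
stand of 50 + 50 adults over a 25-founder pool and 500 saplings.

## Known limitations

* Adult cohorts of realistic size (50–100 per species) give very noisy
  genetic covariances — standard errors comparable to the estimates, and
  occasional non-convergence for the species with less family structure.
  This mirrors the source analysis (whose weakly structured species also
  produced NA cells) and is why the response comparison is sign-based.
* The EM fecundity estimator takes kernels as known; misspecified kernel
  scales bias fecundities toward the spatial configuration.
* The lognormal back-transform is exact only for the log link; other
  non-Gaussian traits would need the general GLMM integrals.
* Two-trait models only; no maternal or dominance effects; no Bayesian
  animal models.
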