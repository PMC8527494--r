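---
title: "Whole-genome regression and GBLUP: models, priors, and design choices"
author: "wgrBayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome regression and GBLUP: models, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Genomic prediction estimates the additive genetic merit (breeding value)
of animals from genome-wide SNP genotypes, using a reference population
with both genotypes and phenotypes to learn marker effects, and predicting
candidates from genotypes alone. This package implements the standard
sheep/cattle-scale workflow: marker quality control, a genomic
relationship matrix, five Bayesian whole-genome regression models, and
k-fold cross-validated accuracy, together with a synthetic-data generator
so every stage is testable end to end.

# Models and priors

All marker models share the linear model
$y = Xb + \sum_j Z_{ij}\alpha_j + e$, with $e_i \sim N(0, \sigma^2_e)$.
$X$ carries an intercept plus reference-level dummy codes for herd and
sex; $b$ gets a flat prior. The prior on the marker effects
$\alpha_j$ defines the family:

* **BayesA** — $\alpha_j \mid \sigma^2_j \sim N(0, \sigma^2_j)$ with
  $\sigma^2_j \sim$ scaled-inv-$\chi^2(\nu, S)$, so marginally a scaled
  $t_\nu$.
* **BayesB** — a point mass at zero with probability $\pi$ and the BayesA
  slab otherwise. $\pi$ is fixed at 0.95 by default (an option estimates
  it with a Beta(1,1) prior).
* **BayesCπ** — a point mass at zero with probability $\pi$, estimated
  via $\pi \sim \mathrm{Beta}(m_0+1, m_1+1)$, and a normal slab with one
  common variance $\sigma^2_\alpha \sim$ scaled-inv-$\chi^2(\nu, S)$;
  integrating the variance makes the slab marginally $t$, i.e. a
  point–$t$ mixture. We implement the exact-zero spike (the "proportion
  of sites with no effect" reading) rather than a narrow second
  component.
* **Bayesian LASSO** — the Park–Casella scale mixture:
  $\alpha_j \mid \tau^2_j \sim N(0, \tau^2_j \sigma^2_e)$,
  $\tau^2_j \sim \mathrm{Exp}(\lambda^2/2)$,
  $\lambda^2 \sim \mathrm{Gamma}$, giving a double-exponential marginal.
* **ridge** — BayesCπ with $\pi$ fixed at 0: a common-variance normal
  prior. Included because it is the marker-side dual of GBLUP.

**GBLUP** fits $y = Xb + u + e$ with $\mathrm{Var}(u) = G\sigma^2_a$ and
$G = W_a W_a^\top / (2\sum_f p_f(1-p_f))$ (VanRaden method 1), where
$W_a$ is the dosage matrix column-centered by $2p_f$. With $G$ built from
the same markers and matched variance scales, GBLUP and ridge give the
same posterior for the genetic values; the test suite asserts this
equivalence (posterior-mean GEBV correlation > 0.99), which cross-checks
the two independently coded samplers against each other.

# Sampling

All models run a single-site Gibbs sampler with residual updating in
compiled code: each coordinate is drawn from its full conditional and the
maintained residual $e = y - Xb - W\alpha$ is updated in place, so an
iteration costs $O(nm)$. GBLUP is sampled in the eigencoordinates of
$G$ (one eigendecomposition up front, then independent univariate
updates); eigenvalues below $10^{-8}\lambda_{max}$ are clamped to that
tolerance and the count is recorded in the fit's settings.

Candidate individuals stay inside the sampler with $y$ missing: their
phenotypes are redrawn from the current model each iteration (data
augmentation), which is exact — an augmented phenotype carries no
information, so training-individual posteriors match a fit with
candidates removed (asserted within Monte Carlo error in the tests).

Two correctness facilities are built in. A `debug` mode recomputes
$W\alpha$ from scratch at every stored iteration and records the maximum
deviation from the maintained residual decomposition (asserted
$<10^{-8}$). And because every draw flows through R's RNG, a seed fixes
the entire chain bit-for-bit.

Markers with zero dosage variance are unidentifiable and keep a zero
effect; they are likewise dropped from the GRM denominator.

# Hyperparameters

Field practice rarely specifies prior scales, so unset scales resolve
from an assumed model $R^2$ (default 0.5), the standard heuristic in
whole-genome regression software: the prior mode of the genetic variance
is set to $R^2 \mathrm{Var}(y)$, spread over markers through
$MS_x = \sum_j \mathrm{Var}(w_j)$ for marker models (divided by $1-\pi$
for the point-mass families), with $\nu = 5$ for all
scaled-inv-$\chi^2$ priors and the residual scale set to
$(1-R^2)\mathrm{Var}(y)$. For the LASSO, $\lambda^2$ starts at
$2 MS_x (1-R^2)/R^2$ and is sampled under a Gamma(1.1, rate) hyperprior
whose mean is that value.

For BayesA and BayesB the scale $S$ is additionally **sampled** under a
conjugate Gamma hyperprior (mode at the heuristic value). This pooling
step matters: with $m \gg n$, a fixed per-marker scaled-inv-$\chi^2$
prior is prior-dominated — every marker keeps injecting slab-level noise
into the sampled genetic values, and the genetic variance (hence $h^2$)
is badly overestimated. Sampling $S$ lets the data shrink all marker
variances jointly; parameter-recovery tests on matched architectures
(below) only pass with this update, and it mirrors what mature samplers
in this field do.

Two numerically delicate points: the inverse-Gaussian sampler for the
LASSO's $1/\tau^2_j$ uses the form
$x = \mu(1 - 2/(1+\sqrt{1+4/u}))$, $u = y\mu/\lambda$, which is
algebraically equal to the textbook Michael–Schucany–Haas expression but
avoids catastrophic cancellation when $\mu \gg \lambda$ (small effects);
and the exact Hardy–Weinberg test enumerates heterozygote counts in log
space, so it is stable at any sample size.

# Quality control

Filters run in a fixed order — non-autosomal, call rate, MAF, exact HWE —
so the report attributes each removed marker to the first filter that
rejects it. Removal is by strict inequality ("below threshold"; defaults
0.95 / 0.01 / 1e-6), so markers exactly at a boundary are kept; this
boundary behaviour is the documented contract and is pinned by tests.
The HWE test is the exact probability-ordering test (not $\chi^2$),
verified against a brute-force enumeration oracle for all totals up to
200. Sporadic missing genotypes are filled from observed allele
frequencies (expected dosage $2\hat p$, or binomial sampling); a
haplotype-based imputer is deliberately out of scope since post-QC
missingness is sporadic and the samplers need only a complete dosage
matrix.

# The synthetic-data generator

The generator emulates the structure the analysis assumes, not a
population-genetic history. Allele frequencies are drawn from a truncated
Beta (default Beta(1,1) on [0.01, 0.99], array-like); two haplotypes per
individual follow a first-order Markov chain with adjacent-allele
correlation `ld_rho` (default 0.3) and are summed to dosages — the
simplest mechanism giving tunable LD without coalescent machinery.
Defaults reflect a flock-scale study: 821 individuals, 7 balanced herds,
two sexes (Bernoulli(0.5)), herd effects of 0.3 and a sex effect of 0.2
phenotypic SD. The marker panels default to 13,000 high-density with a
nested 1,000-marker low-density subset (every k-th marker), preserving
the ~13:1 density ratio of the HD-versus-50K array designs this mimics
at a size where a desk machine can iterate. The default `h2_target` of
0.5 sits mid-range of reported wool-trait heritabilities (≈0.29–0.70).

Marker effects follow the architecture matched to each prior family
(normal, t, point-t, point-normal, Laplace; point families set exactly
`round(prop_qtl × m)` effects nonzero). The residual variance is
calibrated to the **realized** variance of the breeding values so that
`Var(BV)/(Var(BV)+σ²_e)` equals `h2_target` exactly per dataset — this
makes recovery tests sharp instead of fuzzy in the realized signal.

What the generator does *not* emulate: population structure and
relatedness gradients, genotyping error, dominance/epistasis, selection.
Passing tests therefore show the estimators are correct under their own
assumptions, not that real-data accuracies will match.

# Cross-validation

`crossValidate()` draws a fresh uniformly random k-fold partition per
replicate (fold sizes differ by at most one; replicate seeds are
`master + r` for auditability), masks each fold's phenotypes, refits with
the candidates carried as missing, and correlates their GEBVs with
$y^* = y - X\hat b$ using the **training** fixed-effect estimates —
correcting per training fold avoids using validation phenotypes in their
own correction. For marker models the validation dosages are centered
with training-fold allele frequencies. The final accuracy averages all
k × replicates values (5 × 3 by default). A theory sanity band is
asserted in the tests: out-of-sample accuracy cannot exceed
$\sqrt{h^2}$ by more than Monte Carlo noise.

# Validation suite and problem sizes

The package's claims are established by computation, at sizes chosen so
the whole suite iterates comfortably on a single core:

* **Prior reproduction** (Geweke-style): with every phenotype missing the
  chain must reproduce the prior exactly — pooled effect draws match the
  scaled-$t$ (BayesA) and Laplace (fixed-$\lambda$ LASSO) laws by KS test,
  and the BayesCπ point mass holds its fixed $\pi$; run at n = 10–20,
  m = 50 with small scales so successive draws are effectively
  independent.
* **Conjugate closed form**: the intercept-only model matches the
  normal–inverse-$\chi^2$ posterior in moments (within 2%) and
  distribution (KS), at n = 150.
* **GBLUP–ridge equivalence** at n = 200, m = 1000.
* **Parameter recovery**: n = 800, m = 5000, architectures matched to
  priors, `h2_target` ∈ {0.3, 0.5, 0.7}; every model's posterior-mean
  $h^2$ within ±0.1 of truth (chains 9000/3000/3 — sized for stable
  summaries under LD, where single-site samplers mix slowest).
* **Accuracy ordering**: paired generator seeds at h² = 0.3 vs 0.7;
  cross-validated accuracy strictly higher at 0.7 for every model
  (n = 400, m = 1000).
* **GRM oracle**: brute-force double-loop agreement to 1e-10 (50 × 500);
  mean diagonal within 0.05 of 1 under HWE at m = 5000; exact
  counted-allele fold invariance.

Default MCMC settings for analysis use are 15000/5000/5
(iterations/burn-in/thin), single chain; effective-sample-size style
stability is the user's responsibility to check on real data (posterior
SDs are reported, not enforced convergence diagnostics).

# Known limitations

* Single-trait, additive-only models; no permanent-environment or
  maternal effects (no repeated records assumed).
* BayesB's fixed-π default (0.95) is a modeling choice; when the true
  architecture is dense, BayesB with fixed π shrinks too hard — estimate
  π or use BayesCπ.
* The variance components reported for marker models are the per-draw
  variance of the fitted genetic values, which is the natural in-sample
  analogue of $\sigma^2_a$ but inherits sampling noise at small n.
* The PED reader's counted-allele convention (first allele observed per
  marker) makes a bare write→read round trip allele-flip ambiguous for
  markers whose first individual is homozygous for the other allele; all
  downstream quantities are invariant to the flip, and an override list
  restores exact dosage round trips.
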