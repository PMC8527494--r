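# wgrBayes

Genomic prediction of quantitative traits from genome-wide SNP dosages, in
the style used for livestock breeding programs: the **Bayesian alphabet**
of whole-genome regression models (BayesA, BayesB, BayesCπ, Bayesian
LASSO) and **GBLUP**, with marker quality control, the VanRaden genomic
relationship matrix, posterior heritability, and k-fold cross-validated
prediction accuracy. It is aimed at quantitative geneticists who want a
self-contained, testable implementation of the standard genomic-selection
workflow — including a synthetic genotype/phenotype generator so every
stage can be exercised without any external data.

## The models

All marker models fit

```
y = X b + Σ_j Z_ij α_j + e
```

where `y` are phenotypes (herd and sex enter `X b` as fixed effects with
an intercept), `Z_ij ∈ {0,1,2}` is the counted-allele dosage of individual
`i` at marker `j`, and `α_j` are marker effects. The families differ only
in the prior on `α_j`:

| model    | prior on α_j                                               |
|----------|------------------------------------------------------------|
| BayesA   | scaled-t (per-marker variance, scaled-inv-χ² prior)        |
| BayesB   | exact zero with probability π, scaled-t otherwise          |
| BayesCπ  | exact zero with probability π (estimated), common-variance slab |
| B. LASSO | double-exponential via the Park–Casella scale mixture      |
| ridge    | normal with common variance                                 |

GBLUP instead fits `y = X b + u + e` with `Var(u) = G σ²_a`, where

```
G = W_a W_aᵀ / (2 Σ_f p_f (1 − p_f))     (VanRaden method 1)
```

and `W_a` is the dosage matrix with each column centered by twice its
allele frequency. All models are fit by a single-site Gibbs sampler with
residual updating (compiled, Rcpp); GBLUP is sampled in the
eigencoordinates of `G`. Prediction candidates stay inside the sampler
with their phenotypes treated as missing and redrawn each iteration.
Heritability is `h² = σ²_a / (σ²_a + σ²_e)` computed per posterior draw;
prediction accuracy is the Pearson correlation `cor(GEBV, y*)` between
genomic breeding values and phenotypes corrected by the training-fold
fixed-effect estimates, under fivefold cross-validation run in triplicate.

## Worked example

```r
library(wgrBayes)

cfg <- simConfig(n_individuals = 400, n_markers_high = 1500,
                 n_markers_low = 500, architecture = "point_t",
                 prop_qtl = 0.05, h2_target = 0.5, seed = 11)
gm  <- simulateGenotypes(cfg)
qc  <- applyQC(gm)                      # call rate / MAF / HWE / autosomes
gm2 <- imputeSporadic(qc$genotypes)$genotypes
eff <- simulateEffects(1500, "point_t", prop_qtl = 0.05, seed = 12)
sim <- simulatePhenotypes(gm, eff, cfg)

fit <- wgrFit(sim$phenotypes$trait1, buildDesign(sim$phenotypes),
              grm = vanRadenGRM(gm2), prior = priorSpec("gblup"),
              mcmc = mcmcSettings(6000, 2000, 4, seed = 1))
heritability(fit)
#>   estimate         sd
#> 0.54565037 0.09880819

cv <- crossValidate(gm2, sim$phenotypes, models = c("bayesCpi", "gblup"),
                    k = 5, n_replicates = 3, seed = 2,
                    mcmc = mcmcSettings(1500, 500, 2))
cvSummary(cv)
#>      model  trait      mean         se  n
#> 1 bayesCpi trait1 0.3274431 0.01805426 15
#> 2    gblup trait1 0.2634430 0.01701202 15
```

The posterior heritability (0.55 ± 0.10) recovers the simulated target of
0.5 within its uncertainty, and the sparse-architecture trait is predicted
better by BayesCπ (0.33) than by GBLUP (0.26), as expected when a small
fraction of markers carries the signal.

`runPipeline(runConfig(...))` chains all stages (simulate/read → QC →
impute → GRM → fits → CV) and writes TSV artifacts plus a `config.json`
echo whose hash is stamped into every output table.

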