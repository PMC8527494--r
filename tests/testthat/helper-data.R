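# Shared fixture builders: everything is generated in code at test time.

# HWE genotype matrix with known frequencies, no LD, no missingness.
hweGenotypes <- function(n, m, seed = 1, pmin = 0.05, pmax = 0.95) {
  set.seed(seed)
  p <- runif(m, pmin, pmax)
  Z <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  rownames(Z) <- sprintf("i%04d", seq_len(n))
  colnames(Z) <- sprintf("s%05d", seq_len(m))
  GenotypeData(Z)
}

# Additive phenotype with exact target h2 on a given GenotypeData.
additivePhenotype <- function(gm, h2, arch = "normal", prop_qtl = 0.05,
                              seed = 1, mu = 10) {
  Z <- dosages(gm)
  eff <- simulateEffects(ncol(Z), arch, prop_qtl = prop_qtl, seed = seed)
  W <- sweep(Z, 2, colMeans(Z))
  bv <- drop(W %*% eff)
  vb <- var(bv)
  ve <- if (vb > 0) vb * (1 - h2) / h2 else 1
  set.seed(seed + 1)
  y <- mu + bv + rnorm(nrow(Z), 0, sqrt(ve))
  list(y = y, bv = bv, varBV = vb, varE = ve, effects = eff)
}

interceptDesign <- function(ids) {
  structure(list(X = matrix(1, length(ids), 1,
                            dimnames = list(ids, "intercept")),
                 coef_names = "intercept", ids = ids,
                 levels = list()), class = "FixedDesign")
}

# Independent brute-force HWE exact test: enumerate every heterozygote
# count compatible with the allele counts, probability-order, and sum.
hweBruteForce <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- (2 * n - nA - h) / 2
    exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }, 0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hets)] * (1 + 1e-12)])
}

# Constant-draw WgrFit for heritability arithmetic.
constantDrawsFit <- function(varA, varE, ndraws = 10) {
  new("WgrFit", model = "gblup",
      scalarDraws = cbind(varE = rep(varE, ndraws),
                          varG = rep(varA, ndraws)),
      bDraws = matrix(0, ndraws, 0), effects = data.frame(),
      effectDraws = matrix(0, 0, 0), gMean = numeric(0),
      settings = list())
}
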