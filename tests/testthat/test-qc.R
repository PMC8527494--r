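test_that("call rate and MAF are simple counting", {
  expect_equal(markerCallRate(c(0, 1, 2, NA)), 0.75)
  expect_equal(markerCallRate(c(0, 1, 2)), 1.0)
  expect_equal(markerCallRate(c(NA_real_, NA_real_)), 0.0)
  expect_equal(markerMAF(c(0, 0, 0, 1)), 0.125)
  expect_equal(markerMAF(c(2, 2, 2, 2)), 0)
  expect_equal(markerMAF(c(1, 1)), 0.5)
  expect_error(markerMAF(c(NA_real_)), "all-missing")
})

test_that("exact HWE p-values match the enumeration oracle", {
  expect_equal(hweExactPvalue(10, 0, 0), 1)
  expect_gte(hweExactPvalue(25, 50, 25), 0.99)
  expect_error(hweExactPvalue(-1, 2, 3), "negative")
  # heterozygotes-only configurations against the brute-force enumeration
  for (n in c(2, 10, 31)) {
    expect_equal(hweExactPvalue(0, n, 0), hweBruteForce(0, n, 0))
  }
  # random configurations, totals up to 200
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(1:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hweExactPvalue(nAA, nAa, naa),
                 hweBruteForce(nAA, nAa, naa), tolerance = 1e-12)
  }
})

test_that("filters use strict 'below-threshold' removal in fixed order", {
  # 100 individuals: call rate granularity 0.01 brackets the 0.95 boundary
  set.seed(1)
  n <- 100
  d <- cbind(
    at_cr   = c(rep(NA, 5), rbinom(n - 5, 2, 0.5)),   # call rate 0.95: kept
    below_cr = c(rep(NA, 6), rbinom(n - 6, 2, 0.5)),  # 0.94: removed
    low_maf = c(1, rep(0, n - 1)),                    # MAF 0.005: removed
    at_maf  = c(1, 1, rep(0, n - 2)),                 # MAF 0.01: kept
    hwe_bad = rep(1, n),                              # all-het: HWE blowup
    ok      = rbinom(n, 2, 0.4))
  rownames(d) <- sprintf("i%03d", 1:n)
  mk <- data.frame(id = colnames(d),
                   chrom = c("1", "1", "2", "2", "3", "X"),
                   pos = 1:6, allele1 = "A", allele2 = "G",
                   low_panel = TRUE)
  gm <- GenotypeData(d, mk)
  res <- applyQC(gm, qcThresholds())
  rp <- res$report
  expect_identical(rp@removedNonAutosomal, 1L)   # the "ok" column on X
  expect_identical(rp@removedCallRate, 1L)
  expect_identical(rp@removedMaf, 1L)
  expect_identical(rp@removedHwe, 1L)
  expect_identical(markerInfo(res$genotypes)$id, c("at_cr", "at_maf"))
  expect_identical(rp@nMarkersOut,
                   rp@nMarkersIn - rp@removedNonAutosomal -
                     rp@removedCallRate - rp@removedMaf - rp@removedHwe)
  expect_identical(ncol(dosages(res$genotypes)), rp@nMarkersOut)

  # idempotence
  res2 <- applyQC(res$genotypes, qcThresholds())
  expect_equal(dosages(res2$genotypes), dosages(res$genotypes))
  expect_identical(res2$report@nMarkersOut, rp@nMarkersOut)
})

test_that("frequency imputation fills missing cells and nothing else", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  gm <- GenotypeData(d)
  out <- imputeSporadic(gm, "expected_dosage")
  expect_equal(dosages(out$genotypes)["c", "s1"], 1.0)  # 2 * p = 1
  expect_equal(out$n_imputed, 1L)
  expect_equal(dosages(out$genotypes)[-3, 1], d[-3, 1])

  full <- imputeSporadic(GenotypeData(matrix(c(0, 1, 2), 3, 1,
    dimnames = list(letters[1:3], "s"))), "expected_dosage")
  expect_equal(full$n_imputed, 0L)

  s1 <- imputeSporadic(gm, "sampled", seed = 3)
  s2 <- imputeSporadic(gm, "sampled", seed = 3)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_true(dosages(s1$genotypes)["c", "s1"] %in% c(0, 1, 2))

  dAllNA <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_error(imputeSporadic(GenotypeData(dAllNA)), "all-missing")
})
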