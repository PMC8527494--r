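test_that("genotype simulation is deterministic and respects config", {
  cfg <- simConfig(n_individuals = 50, n_markers_high = 120,
                   n_markers_low = 30, missing_rate = 0.02, seed = 7)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosages(g1), dosages(g2))
  expect_identical(markerInfo(g1), markerInfo(g2))
  expect_true(all(dosages(g1) %in% c(0, 1, 2, NA)))
  expect_equal(sum(markerInfo(g1)$low_panel), 30)
  expect_true(all(markerInfo(g1)$chrom %in% as.character(1:26)))

  g0 <- simulateGenotypes(simConfig(n_individuals = 50,
                                    n_markers_high = 120,
                                    n_markers_low = 30,
                                    missing_rate = 0, seed = 7))
  expect_false(anyNA(dosages(g0)))
  expect_error(simConfig(n_individuals = 1), "n_individuals")
})

test_that("ld_rho = 0 gives uncorrelated adjacent markers, ld_rho > 0 correlated", {
  cfg0 <- simConfig(n_individuals = 2000, n_markers_high = 200,
                    n_markers_low = 50, ld_rho = 0, missing_rate = 0,
                    seed = 11)
  d <- dosages(simulateGenotypes(cfg0))
  adj <- vapply(seq_len(ncol(d) - 1L),
                function(j) cor(d[, j], d[, j + 1L]), 0)
  expect_lt(mean(abs(adj)), 0.05)

  cfg5 <- simConfig(n_individuals = 2000, n_markers_high = 200,
                    n_markers_low = 50, ld_rho = 0.5, missing_rate = 0,
                    freq_beta_a = 3, freq_beta_b = 3, seed = 11)
  d5 <- dosages(simulateGenotypes(cfg5))
  adj5 <- vapply(seq_len(ncol(d5) - 1L),
                 function(j) cor(d5[, j], d5[, j + 1L]), 0)
  expect_gt(mean(adj5), 0.3)
})

test_that("allele-frequency spectrum matches the configured Beta", {
  cfg <- simConfig(n_individuals = 400, n_markers_high = 10000,
                   n_markers_low = 1000, freq_beta_a = 2, freq_beta_b = 2,
                   missing_rate = 0, ld_rho = 0, seed = 3)
  gm <- simulateGenotypes(cfg)
  freq <- alleleFreqs(gm)
  # sample frequencies estimate the drawn Beta(2,2) frequencies with
  # binomial noise SD ~ sqrt(pq/2n) ~ 0.017; compare against the Beta CDF
  ks <- suppressWarnings(ks.test(freq, function(q) pbeta(q, 2, 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("effect architectures match their families", {
  e <- simulateEffects(1000, "point_t", prop_qtl = 0.01, seed = 1)
  expect_identical(sum(e != 0), 10L)
  e2 <- simulateEffects(1000, "point_normal", prop_qtl = 0.25, seed = 1)
  expect_identical(sum(e2 != 0), 250L)
  expect_error(simulateEffects(10, "cauchy"), "unknown architecture")

  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  en <- simulateEffects(1e5, "normal", seed = 2)
  expect_gt(kurt(en), 2.8)
  expect_lt(kurt(en), 3.2)
  el <- simulateEffects(1e5, "laplace", seed = 2)
  expect_gt(kurt(el) - 3, 2.7)   # Laplace excess kurtosis = 3
  expect_lt(kurt(el) - 3, 3.3)
})

test_that("phenotype simulation hits the target heritability exactly", {
  cfg <- simConfig(n_individuals = 300, n_markers_high = 400,
                   n_markers_low = 100, h2_target = 0.5,
                   missing_rate = 0.01, seed = 5)
  gm <- simulateGenotypes(cfg)
  eff <- simulateEffects(400, "normal", seed = 6)
  sim <- simulatePhenotypes(gm, eff, cfg)
  expect_equal(sim$truth$realized_h2, 0.5, tolerance = 1e-12)
  # true_bv = centered dosage %*% effects to machine precision
  Z <- dosages(gm)
  cm <- colMeans(Z, na.rm = TRUE)
  for (j in which(colSums(is.na(Z)) > 0)) Z[is.na(Z[, j]), j] <- cm[j]
  W <- sweep(Z, 2, cm)
  expect_equal(sim$truth$true_bv, drop(W %*% eff), tolerance = 1e-12)
  expect_equal(var(sim$truth$true_bv) /
                 (var(sim$truth$true_bv) + sim$truth$varE), 0.5,
               tolerance = 1e-12)

  simz <- simulatePhenotypes(gm, numeric(400), cfg)
  expect_true(all(simz$truth$true_bv == 0))
  expect_identical(simz$truth$realized_h2, 0)
  expect_error(simulatePhenotypes(gm, numeric(10), cfg), "dimension")
})

test_that("written datasets round-trip and are byte-identical under a seed", {
  cfg <- simConfig(n_individuals = 30, n_markers_high = 60,
                   n_markers_low = 20, missing_rate = 0.02, seed = 9)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  out1 <- makeDataset(cfg, d1)
  out2 <- makeDataset(cfg, d2)
  for (f in c("ped", "map", "low_panel", "phenotypes", "truth"))
    expect_identical(readLines(out1$paths[[f]]), readLines(out2$paths[[f]]))
  expect_length(readLines(out1$paths$low_panel), 20)

  gm <- out1$genotypes
  back <- readPlinkText(out1$paths$ped, out1$paths$map,
                        counted_alleles = setNames(markerInfo(gm)$allele1,
                                                   markerInfo(gm)$id))
  expect_equal(dosages(back), dosages(gm))
  phen <- readPhenotypes(out1$paths$phenotypes)
  expect_equal(phen$trait1, out1$phenotypes$trait1)
  expect_identical(phen$id, out1$phenotypes$id)
})
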