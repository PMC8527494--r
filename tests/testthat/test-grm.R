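test_that("single-marker GRM matches the hand computation", {
  d <- matrix(c(0, 1, 2), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  g <- vanRadenGRM(GenotypeData(d))
  expect_equal(g@denominator, 0.5)
  expect_equal(unname(grmMatrix(g)),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))
  expect_equal(alleleFreqs(GenotypeData(d)), c(s1 = 0.5))
  expect_equal(alleleFreqs(GenotypeData(matrix(c(2, 2, 2), 3, 1,
    dimnames = list(letters[1:3], "s")))), c(s = 1.0))
})

test_that("GRM equals the brute-force double-loop evaluation", {
  gm <- hweGenotypes(50, 500, seed = 8)
  g <- vanRadenGRM(gm)
  d <- dosages(gm)
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  G2 <- matrix(0, 50, 50)
  for (i in 1:50) for (k in i:50) {
    s <- 0
    for (j in which(keep))
      s <- s + (d[i, j] - 2 * p[j]) * (d[k, j] - 2 * p[j])
    G2[i, k] <- G2[k, i] <- s / denom
  }
  expect_lt(max(abs(unname(grmMatrix(g)) - G2)), 1e-10)
  # centering identity: row sums of G vanish at observed frequencies
  expect_lt(max(abs(rowSums(grmMatrix(g)))),
            1e-8 * max(abs(grmMatrix(g))))
  # PSD up to numerical tolerance
  ev <- eigen(grmMatrix(g), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("GRM is invariant to which allele is counted", {
  gm <- hweGenotypes(30, 200, seed = 9)
  g1 <- grmMatrix(vanRadenGRM(gm))
  flip <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  d2 <- dosages(gm)
  d2[, flip] <- 2 - d2[, flip]
  g2 <- grmMatrix(vanRadenGRM(GenotypeData(d2, markerInfo(gm))))
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("identical individuals get identical relationships", {
  d <- dosages(hweGenotypes(10, 100, seed = 10))
  d[2, ] <- d[1, ]
  g <- grmMatrix(vanRadenGRM(GenotypeData(d)))
  expect_equal(g[1, 1], g[2, 2], tolerance = 1e-12)
  expect_equal(g[1, 1], g[1, 2], tolerance = 1e-12)
  expect_equal(g[1, ], g[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("monomorphic handling and serialization round-trip", {
  d <- cbind(dosages(hweGenotypes(10, 20, seed = 11)),
             mono = rep(2, 10))
  gm <- GenotypeData(d)
  expect_error(vanRadenGRM(gm, drop_monomorphic = FALSE), "monomorphic")
  g <- vanRadenGRM(gm)                       # dropped from denominator
  expect_error(vanRadenGRM(GenotypeData(matrix(2, 5, 2,
    dimnames = list(letters[1:5], c("a", "b"))))), "monomorphic")

  path <- file.path(tempdir(), "g.tsv")
  writeGRM(g, path)
  back <- readGRM(path)
  expect_equal(grmMatrix(back), grmMatrix(g), tolerance = 1e-8)
  expect_equal(back@denominator, g@denominator, tolerance = 1e-8)
})
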