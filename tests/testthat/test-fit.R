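test_that("design matrix uses reference-level dummy coding", {
  ph <- data.frame(id = c("a", "b", "c", "d"),
                   herd = c("h1", "h2", "h1", "h2"),
                   sex = c("F", "M", "M", "F"))
  des <- buildDesign(ph)
  expect_identical(colnames(des$X), c("intercept", "herdh2", "sexM"))
  expect_equal(unname(des$X[, "herdh2"]), c(0, 1, 0, 1))
  expect_equal(unname(des$X[, "sexM"]), c(0, 1, 1, 0))

  ph1 <- ph; ph1$herd <- "h1"
  expect_message(des1 <- buildDesign(ph1), "single level")
  expect_identical(colnames(des1$X), c("intercept", "sexM"))

  ph2 <- ph; ph2$sex[2] <- "unknown"
  expect_error(buildDesign(ph2), "unknown sex label")
  ph3 <- ph; ph3$sex <- c("male", "Female", "F", "m")
  expect_silent(buildDesign(ph3))
  # first observed level (M) is the reference, so the dummy is sexF
  expect_equal(unname(buildDesign(ph3)$X[, "sexF"]), c(0, 1, 1, 0))
})

test_that("posterior heritability is the per-draw variance ratio", {
  expect_equal(round(heritability(constantDrawsFit(89.63, 37.73))[["estimate"]],
                     2), 0.70)
  expect_equal(round(heritability(constantDrawsFit(26.47, 20.77))[["estimate"]],
                     2), 0.56)
  f0 <- constantDrawsFit(0, 5)
  expect_equal(heritability(f0)[["estimate"]], 0)
  # per-draw averaging, not ratio of averages
  f <- new("WgrFit", model = "gblup",
           scalarDraws = cbind(varE = c(1, 1), varG = c(1, 3)),
           bDraws = matrix(0, 2, 0), effects = data.frame(),
           effectDraws = matrix(0, 0, 0), gMean = numeric(0),
           settings = list())
  expect_equal(heritability(f)[["estimate"]], mean(c(0.5, 0.75)))
})

test_that("chains are reproducible and the maintained residual is exact", {
  gm <- hweGenotypes(80, 120, seed = 20)
  sim <- additivePhenotype(gm, 0.5, seed = 21)
  des <- interceptDesign(individualIds(gm))
  mc <- mcmcSettings(600, 100, 5, seed = 33)
  for (fam in c("bayesA", "bayesB", "bayesCpi", "blasso")) {
    f1 <- wgrFit(sim$y, des, genotypes = gm, prior = priorSpec(fam),
                 mcmc = mc, debug = TRUE)
    f2 <- wgrFit(sim$y, des, genotypes = gm, prior = priorSpec(fam),
                 mcmc = mc)
    expect_identical(f1@scalarDraws, f2@scalarDraws)
    expect_identical(f1@effects$mean, f2@effects$mean)
    expect_lt(f1@settings$resid_dev, 1e-8)
    expect_identical(nrow(f1@scalarDraws), 100L)
    expect_true(all(f1@scalarDraws[, "varE"] > 0))
  }
  g <- vanRadenGRM(gm)
  f1 <- wgrFit(sim$y, des, grm = g, prior = priorSpec("gblup"),
               mcmc = mc, debug = TRUE)
  f2 <- wgrFit(sim$y, des, grm = g, prior = priorSpec("gblup"), mcmc = mc)
  expect_identical(f1@scalarDraws, f2@scalarDraws)
  expect_lt(f1@settings$resid_dev, 1e-8)
})

test_that("gebv reproduces fitted genetic values and handles new dosages", {
  gm <- hweGenotypes(60, 100, seed = 22)
  sim <- additivePhenotype(gm, 0.5, seed = 23)
  des <- interceptDesign(individualIds(gm))
  fit <- wgrFit(sim$y, des, genotypes = gm, prior = priorSpec("ridge"),
                mcmc = mcmcSettings(800, 300, 5, seed = 2))
  # training-dosage gebv equals alphaMean-based projection of gMean
  g1 <- gebv(fit, gm)
  expect_equal(unname(g1), unname(gebv(fit)), tolerance = 1e-8)
  # duplicate rows give identical predictions
  d2 <- dosages(gm)[c(1, 1, 2), ]
  rownames(d2) <- c("x1", "x2", "x3")
  g2 <- gebv(fit, d2)
  expect_equal(g2[1], g2[2], ignore_attr = TRUE)
  # zero posterior-mean effects give zero gebv
  fit0 <- fit
  fit0@effects$mean <- rep(0, nrow(fit0@effects))
  expect_true(all(gebv(fit0, gm) == 0))
  expect_error(gebv(fit, dosages(gm)[, 1:10]), "marker mismatch")
  gfit <- wgrFit(sim$y, des, grm = vanRadenGRM(gm),
                 prior = priorSpec("gblup"),
                 mcmc = mcmcSettings(800, 300, 5, seed = 2))
  expect_named(gebv(gfit, ids = individualIds(gm)[1:3]))
  expect_error(gebv(gfit, ids = "nope"), "not in the fitted GRM")
})

test_that("marker order exchangeability: permuting markers permutes effects", {
  gm <- hweGenotypes(150, 80, seed = 24)
  sim <- additivePhenotype(gm, 0.6, seed = 25)
  des <- interceptDesign(individualIds(gm))
  mc <- mcmcSettings(3000, 1000, 2, seed = 5)
  fit1 <- wgrFit(sim$y, des, genotypes = gm, prior = priorSpec("bayesCpi"),
                 mcmc = mc)
  perm <- rev(seq_len(80))
  gmP <- gm[, perm]
  fit2 <- wgrFit(sim$y, des, genotypes = gmP, prior = priorSpec("bayesCpi"),
                 mcmc = mc)
  # posterior means agree within MC error after unpermuting
  expect_gt(cor(fit1@effects$mean, fit2@effects$mean[order(perm)]), 0.95)
  expect_gt(cor(gebv(fit1), gebv(fit2)), 0.99)
  expect_lt(abs(heritability(fit1)[["estimate"]] -
                heritability(fit2)[["estimate"]]), 0.05)
})

test_that("candidates carried as missing y match dropping them from training", {
  gm <- hweGenotypes(200, 150, seed = 26)
  sim <- additivePhenotype(gm, 0.6, seed = 27)
  des <- interceptDesign(individualIds(gm))
  y <- sim$y
  val <- 151:200
  yMask <- y; yMask[val] <- NA
  mc <- mcmcSettings(4000, 1000, 3, seed = 6)
  tf <- colMeans(dosages(gm)[-val, ]) / 2
  fitMask <- wgrFit(yMask, des, genotypes = gm, prior = priorSpec("ridge"),
                    mcmc = mc, train_freqs = tf)
  gmTrain <- gm[-val, ]
  fitDrop <- wgrFit(y[-val], interceptDesign(individualIds(gmTrain)),
                    genotypes = gmTrain, prior = priorSpec("ridge"),
                    mcmc = mc, train_freqs = tf)
  # training-individual genetic values agree within MC error
  expect_gt(cor(gebv(fitMask)[-val], gebv(fitDrop)), 0.98)
  expect_lt(abs(heritability(fitMask)[["estimate"]] -
                heritability(fitDrop)[["estimate"]]), 0.07)
})
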