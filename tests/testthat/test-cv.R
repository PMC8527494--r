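test_that("k-fold assignment gives near-equal folds, deterministically", {
  ids <- sprintf("i%04d", 1:821)
  f <- kfoldAssign(ids, 5, seed = 1)
  expect_identical(as.integer(sort(table(f), decreasing = TRUE)),
                   c(165L, 164L, 164L, 164L, 164L))
  expect_identical(f, kfoldAssign(ids, 5, seed = 1))
  expect_false(identical(f, kfoldAssign(ids, 5, seed = 2)))
  expect_length(f, 821)

  f10 <- kfoldAssign(letters[1:10], 5, seed = 3)
  expect_true(all(table(f10) == 2))
  expect_error(kfoldAssign(letters[1:3], 5), "k <= n")
})

test_that("corrected phenotype removes training fixed-effect estimates", {
  y <- c(10, 12, 14)
  X <- cbind(intercept = 1, herdB = c(0, 1, 1))
  expect_equal(correctedPhenotype(y, X, c(0, 0)), y)
  expect_equal(correctedPhenotype(y, X, c(mean(y), 0)), y - mean(y))
  # known herd effects: intercept 9, herd B adds 3
  expect_equal(correctedPhenotype(y, X, c(9, 3)), c(1, 0, 2))
  expect_error(correctedPhenotype(y, X, c(1, 2, 3)), "columns")
})

test_that("accuracy is the Pearson correlation with its guard rails", {
  ys <- c(1.2, -0.5, 2.2, 0.1)
  expect_equal(predictionAccuracy(ys, ys), 1.0)
  expect_equal(predictionAccuracy(-ys, ys), -1.0)
  expect_equal(round(predictionAccuracy(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  # invariance to positive affine rescaling
  expect_equal(predictionAccuracy(2.5 * ys + 1, ys),
               predictionAccuracy(ys, ys))
  expect_error(predictionAccuracy(rep(1, 4), ys), "zero variance")
  expect_error(predictionAccuracy(ys, ys[1:3]))
})

test_that("cross-validation is replicable and its summary recomputable", {
  cfg <- simConfig(n_individuals = 150, n_markers_high = 200,
                   n_markers_low = 60, h2_target = 0.6,
                   missing_rate = 0, seed = 30)
  gm <- simulateGenotypes(cfg)
  eff <- simulateEffects(200, "normal", seed = 31)
  sim <- simulatePhenotypes(gm, eff, cfg)
  mc <- mcmcSettings(600, 200, 4, seed = 1)
  cv <- crossValidate(gm, sim$phenotypes, models = c("ridge", "gblup"),
                      k = 5, n_replicates = 2, seed = 44, mcmc = mc)
  f <- cvFolds(cv)
  expect_identical(nrow(f), 2L * 5L * 2L)
  expect_true(all(abs(f$accuracy) <= 1))
  s <- cvSummary(cv)
  for (i in seq_len(nrow(s))) {
    a <- f$accuracy[f$model == s$model[i]]
    expect_equal(s$mean[i], mean(a))
    expect_equal(s$se[i], sd(a) / sqrt(length(a)))
  }
  cv2 <- crossValidate(gm, sim$phenotypes, models = c("ridge", "gblup"),
                       k = 5, n_replicates = 2, seed = 44, mcmc = mc)
  expect_identical(cvFolds(cv2)$accuracy, f$accuracy)
})

test_that("a heritability-zero trait yields null accuracy", {
  cfg <- simConfig(n_individuals = 500, n_markers_high = 1000,
                   n_markers_low = 200, h2_target = 0.5,
                   missing_rate = 0, seed = 32)
  gm <- simulateGenotypes(cfg)
  phen <- simulatePhenotypes(gm, numeric(1000), cfg)$phenotypes
  # zero effects: phenotype is herd + sex + pure noise
  cv <- crossValidate(gm, phen, models = c("bayesCpi", "gblup"), k = 5,
                      n_replicates = 3, seed = 9,
                      mcmc = mcmcSettings(900, 300, 3, seed = 1))
  s <- cvSummary(cv)
  expect_true(all(abs(s$mean) < 0.1))
})
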