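test_that("class weights are inverse frequencies with mean 1 when balanced", {
  expect_equal(unname(classWeights(c(MEL = 692, BEN = 692))), c(1, 1))
  expect_equal(unname(classWeights(c(MEL = 100, BEN = 300))),
               c(2, 2 / 3), tolerance = 1e-12)
  expect_error(classWeights(c(MEL = 100)), "two classes")
  expect_error(classWeights(c(MEL = 0, BEN = 5)), "positive")
})

test_that("weighted cross-entropy matches hand values and scales in w", {
  # perfect one-hot predictions: zero loss up to the clamping epsilon
  P <- rbind(c(1, 0), c(0, 1)); T2 <- P
  expect_lt(weightedCrossEntropy(P, T2), 1e-10)
  # N=1, uniform prediction: -log 0.5
  expect_equal(weightedCrossEntropy(rbind(c(0.5, 0.5)), rbind(c(1, 0))),
               -log(0.5), tolerance = 1e-12)
  # linear in the class weights
  P3 <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.6, 0.4))
  T3 <- rbind(c(1, 0), c(0, 1), c(0, 1))
  w <- c(1.3, 0.6)
  expect_equal(weightedCrossEntropy(P3, T3, 2 * w),
               2 * weightedCrossEntropy(P3, T3, w), tolerance = 1e-12)
  expect_error(weightedCrossEntropy(P3, T3[1:2, ]), "dimensions")
  expect_error(weightedCrossEntropy(P3, T3, c(1, 2, 3)), "length")
})

test_that("weighted cross-entropy equals a per-sample summation oracle", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      n <- sample(3:40, 1)
      p1 <- runif(n)
      P <- cbind(p1, 1 - p1)
      lab <- sample(1:2, n, replace = TRUE)
      T1 <- cbind(lab == 1, lab == 2) * 1
      w <- runif(2, 0.2, 3)
      # brute force: loop sample by sample, class by class
      acc <- 0
      for (i in 1:n) for (j in 1:2)
        acc <- acc - w[j] * T1[i, j] * log(max(P[i, j], 1e-12))
      expect_equal(weightedCrossEntropy(P, T1, w), acc / n,
                   tolerance = 1e-10)
    }
  })
})

test_that("the SGDM update follows classical momentum with L2 decay", {
  cfg <- function(lr = 0.001, mom = 0.99, wd = 0)
    new("TrainConfig", learningRate = lr, momentum = mom, weightDecay = wd)
  # zero gradient, zero velocity: pure decay step
  up <- sgdmStep(2, 0, 0, cfg(wd = 5e-4))
  expect_equal(up$theta, 2 * (1 - 0.001 * 5e-4), tolerance = 1e-15)
  # gamma = 0, lambda = 0 reduces to plain gradient descent
  up2 <- sgdmStep(1, 0.5, 0, cfg(mom = 0))
  expect_equal(up2$theta, 1 - 0.001 * 0.5, tolerance = 1e-15)
  # hand iteration, two steps at constant gradient
  s1 <- sgdmStep(1, 0.5, 0, cfg())
  expect_equal(s1$theta, 0.9995, tolerance = 1e-12)
  s2 <- sgdmStep(s1$theta, 0.5, s1$velocity, cfg())
  expect_equal(s2$velocity, -0.000995, tolerance = 1e-12)
  expect_equal(s2$theta, 0.998505, tolerance = 1e-12)

  expect_error(sgdmStep(1, c(1, 2), 0, cfg()), "shapes")
  expect_error(sgdmStep(1, NaN, 0, cfg()), "non-finite")
})

test_that("a small network memorizes a 10-sample fixture monotonically", {
  d <- small_synth()
  r <- records(d$manifest)
  ids <- c(r$id[r$label == "MEL"][1:5], r$id[r$label == "BEN"][1:5])
  vids <- c(r$id[r$label == "MEL"][6:7], r$id[r$label == "BEN"][6:7])
  pp <- lapply(d$images[c(ids, vids)], preprocessImage)
  labs <- setNames(r$label, r$id)
  net <- buildNetwork(lcnetConfig(), seed = 2)
  cfg <- new("TrainConfig", maxEpochs = 5L, seed = 2L, augment = FALSE)
  fit <- trainNetwork(net, pp[ids], labs[ids], pp[vids], labs[vids], cfg)
  losses <- fit$history@epochs$train_loss
  expect_length(losses, 5L)
  expect_true(all(diff(losses) < 0))
})

test_that("early stopping halts after the patience window", {
  # a frozen network produces a constant validation loss: with patience 1
  # the second epoch already triggers the stop, and epoch 1 stays best
  es <- earlyStopStatus(c(0.7, 0.7), patience = 1L)
  expect_true(es$stop)
  expect_equal(es$bestEpoch, 1L)
  expect_false(earlyStopStatus(0.7, patience = 1L)$stop)
  # ties are not improvements; genuine improvement resets the window
  expect_false(earlyStopStatus(c(0.7, 0.6, 0.55), patience = 2L)$stop)
  expect_true(earlyStopStatus(c(0.7, 0.6, 0.61, 0.6), patience = 2L)$stop)
  expect_equal(earlyStopStatus(c(0.7, 0.6, 0.61, 0.6), patience = 2L)$bestEpoch,
               2L)
  # a long plateau after an early minimum stops patience epochs later
  es2 <- earlyStopStatus(c(0.5, rep(0.5, 3)), patience = 3L)
  expect_true(es2$stop)
  expect_equal(es2$bestEpoch, 1L)
})

test_that("training is deterministic end-to-end for a fixed seed", {
  d <- small_synth()
  r <- records(d$manifest)
  ids <- c(r$id[r$label == "MEL"][1:3], r$id[r$label == "BEN"][1:3])
  vids <- c(r$id[r$label == "MEL"][4], r$id[r$label == "BEN"][4])
  pp <- lapply(d$images[c(ids, vids)], preprocessImage)
  labs <- setNames(r$label, r$id)
  run <- function() {
    net <- buildNetwork(lcnetConfig(), seed = 4)
    cfg <- new("TrainConfig", maxEpochs = 2L, seed = 9L, augment = TRUE)
    trainNetwork(net, pp[ids], labs[ids], pp[vids], labs[vids], cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history@epochs, f2$history@epochs)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("train/validation record sets must be disjoint and non-empty", {
  d <- small_synth()
  r <- records(d$manifest)
  ids <- r$id[1:4]
  pp <- lapply(d$images[ids], preprocessImage)
  labs <- setNames(r$label, r$id)
  net <- buildNetwork(lcnetConfig(), seed = 1)
  expect_error(trainNetwork(net, pp, labs[ids], pp, labs[ids]),
               "disjoint")
  expect_error(trainNetwork(net, list(), character(), pp, labs[ids]),
               "non-empty")
})
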