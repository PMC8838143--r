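test_that("confusion counts tally MEL as positive", {
  expect_equal(unname(confusionCounts(rep("MEL", 5), rep("MEL", 5))),
               c(5L, 0L, 0L, 0L))
  expect_equal(unname(confusionCounts(rep("BEN", 4), rep("MEL", 4))),
               c(0L, 0L, 0L, 4L))
  cc <- confusionCounts(c("MEL", "MEL", "BEN", "BEN", "MEL"),
                        c("MEL", "BEN", "BEN", "MEL", "MEL"))
  expect_equal(unname(cc), c(2L, 1L, 1L, 1L))
  expect_error(confusionCounts("MEL", c("MEL", "BEN")), "length")
})

test_that("metrics evaluate their formulas exactly", {
  rep1 <- evalMetrics(c(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(unname(rep1@metrics["ACC"]), 0.85)
  expect_equal(unname(rep1@metrics["PRE"]), 8 / 9)
  expect_equal(unname(rep1@metrics["REC"]), 0.8)
  expect_equal(unname(rep1@metrics["SPE"]), 0.9)
  expect_equal(unname(rep1@metrics["F1"]), 16 / 19)
  expect_false(rep1@degenerate)

  perfect <- evalMetrics(c(TP = 3, FP = 0, TN = 4, FN = 0))
  expect_equal(unname(perfect@metrics), rep(1, 5))

  worst <- evalMetrics(c(TP = 0, FP = 2, TN = 0, FN = 2))
  expect_equal(unname(worst@metrics[c("ACC", "F1")]), c(0, 0))

  degen <- evalMetrics(c(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_true(degen@degenerate)           # PRE, REC, F1 denominators vanish
  expect_equal(unname(degen@metrics["PRE"]), 0)

  expect_error(evalMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "at least one")
})

test_that("metrics agree with a per-sample tally oracle on random vectors", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(5:200, 1)
      truth <- sample(c("MEL", "BEN"), n, replace = TRUE)
      pred <- sample(c("MEL", "BEN"), n, replace = TRUE)
      cc <- confusionCounts(pred, truth)
      # independent tally
      tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
      for (j in seq_len(n)) {
        if (pred[j] == "MEL" && truth[j] == "MEL") tp <- tp + 1L
        else if (pred[j] == "MEL") fp <- fp + 1L
        else if (truth[j] == "BEN") tn <- tn + 1L
        else fn <- fn + 1L
      }
      expect_equal(unname(cc), c(tp, fp, tn, fn))
      m <- evalMetrics(cc)@metrics
      expect_equal(unname(m["ACC"]), mean(pred == truth))
    }
  })
})

test_that("ROC/AUC matches its closed-form and pairwise-counting oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1),
                      c("MEL", "MEL", "BEN", "BEN"))$auc, 1.0)
  expect_equal(rocAuc(rep(0.5, 6), rep(c("MEL", "BEN"), 3))$auc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2),
                      c("MEL", "BEN", "MEL", "BEN"))$auc, 0.75)
  expect_error(rocAuc(c(0.1, 0.9), c("MEL", "MEL")), "both classes")

  pair_auc <- function(s, y) {
    pos <- s[y == "MEL"]; neg <- s[y == "BEN"]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:200, 1)
      y <- c("MEL", "BEN", sample(c("MEL", "BEN"), n - 2, replace = TRUE))
      s <- round(runif(n), 2)  # rounding forces ties
      r <- rocAuc(s, y)
      expect_equal(r$auc, pair_auc(s, y), tolerance = 1e-12)
      expect_true(all(diff(r$rocPoints$FPR) >= 0))     # monotone sweep
      expect_equal(r$rocPoints$FPR[1], 0)
      expect_equal(r$rocPoints$TPR[nrow(r$rocPoints)], 1)
    }
  })
})

test_that("recall equals the TPR of the 0.5-threshold ROC point", {
  withr::with_seed(29, {
    s <- runif(60)
    s <- s[abs(s - 0.5) > 1e-6]
    y <- ifelse(runif(length(s)) < 0.5, "MEL", "BEN")
    y[1:2] <- c("MEL", "BEN")
  })
  pred <- ifelse(s > 0.5, "MEL", "BEN")
  rec <- evalMetrics(confusionCounts(pred, y))@metrics["REC"]
  expect_equal(unname(rec), mean(s[y == "MEL"] >= 0.5))
})

test_that("ROC/AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    y <- sample(c("MEL", "BEN"), 80, replace = TRUE)
    y[1:2] <- c("MEL", "BEN")
    s <- round(runif(80), 2)
  })
  a1 <- rocAuc(s, y)$auc
  a2 <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                       levels = c("BEN", "MEL"),
                                       direction = "<", quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("model evaluation assembles a coherent report", {
  model <- buildNetwork(lcnetConfig(), seed = 7)
  d <- small_synth()
  r <- records(d$manifest)
  ids <- c(r$id[r$label == "MEL"][1:4], r$id[r$label == "BEN"][1:4])
  pp <- lapply(d$images[ids], preprocessImage)
  rep1 <- evaluateModel(model, pp, setNames(r$label, r$id)[ids])
  expect_s4_class(rep1, "EvalReport")
  expect_equal(sum(rep1@counts), 8L)
  expect_true(rep1@auc >= 0 && rep1@auc <= 1)
  expect_true(all(rep1@metrics >= 0 & rep1@metrics <= 1))
})
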