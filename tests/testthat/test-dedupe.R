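test_that("grayscale conversion applies the luma weights", {
  expect_true(all(toGrayscale(const_img(2, 2, 255)) == 255))
  expect_true(all(toGrayscale(const_img(2, 2, 0)) == 0))
  red <- array(rep(c(255, 0, 0), each = 4), c(2, 2, 3))
  expect_equal(toGrayscale(red)[1, 1], 0.299 * 255)
})

test_that("intensity histograms count every pixel", {
  g <- matrix(c(0, 0, 255, 128.7), 2, 2)
  h <- grayHistogram(g)
  expect_length(h, 256L)
  expect_equal(sum(h), 4L)
  expect_equal(h[1], 2L)     # bin 0
  expect_equal(h[256], 1L)   # bin 255
  expect_equal(h[129], 1L)   # 128.7 truncates to bin 128
})

test_that("image correlation matches its closed-form cases", {
  a <- toGrayscale(rand_img(8, 8, seed = 2))
  expect_equal(imageCorrelation(a, a), 1.0)
  expect_equal(imageCorrelation(a, 255 - a), -1.0)
  # orthogonal centered patterns: hand evaluation gives 0
  expect_equal(imageCorrelation(rbind(c(0, 0), c(10, 10)),
                                rbind(c(0, 10), c(0, 10))), 0)
  # constant image: defined 0 with a warning
  expect_warning(z <- imageCorrelation(matrix(5, 3, 3), a[1:3, 1:3]),
                 "constant")
  expect_equal(z, 0)
})

test_that("correlation is symmetric, affine-invariant and matches Pearson", {
  for (i in 1:20) {
    a <- toGrayscale(rand_img(12, 12, seed = 100 + i))
    b <- toGrayscale(rand_img(12, 12, seed = 200 + i))
    expect_equal(imageCorrelation(a, b), imageCorrelation(b, a),
                 tolerance = 1e-12)
    alpha <- runif(1, 0.1, 3); beta <- runif(1, -20, 20)
    expect_equal(imageCorrelation(a, alpha * a + beta), 1.0,
                 tolerance = 1e-12)
    # independent oracle: Pearson on the flattened grids
    expect_equal(imageCorrelation(a, b),
                 stats::cor(as.numeric(a), as.numeric(b)),
                 tolerance = 1e-12)
  }
})

test_that("differently sized images are aligned before correlating", {
  # a smooth scene survives resampling; its decimated copy stays correlated
  g <- outer(seq(0, 200, length.out = 64), seq(0, 1, length.out = 48),
             function(r, c) r * (0.5 + c / 2))
  big <- array(rep(g, 3), c(64, 48, 3))
  small <- big[seq(1, 64, by = 2), seq(1, 48, by = 2), , drop = FALSE]
  cc <- imageCorrelation(toGrayscale(big), toGrayscale(small))
  expect_true(cc > 0.99 && cc <= 1)
  # and two unrelated noise fields do not become duplicates by resizing
  n1 <- toGrayscale(rand_img(40, 30, seed = 5))
  n2 <- toGrayscale(rand_img(20, 15, seed = 6))
  expect_lt(abs(imageCorrelation(n1, n2)), 0.5)
})

test_that("histogram mode correlates intensity distributions", {
  a <- toGrayscale(rand_img(16, 16, seed = 31))
  expect_equal(imageCorrelation(a, a + 0, mode = "histogram"), 1.0)
  # a constant shift moves the histogram: pixel mode still 1, histogram not
  expect_lt(imageCorrelation(a, a + 40, mode = "histogram"), 0.999)
})

test_that("deduplicate keeps first occurrences and drops exact copies", {
  A <- rand_img(16, 16, seed = 7)
  B <- rand_img(16, 16, seed = 8)
  rep1 <- deduplicate(list(A = A, A2 = A, B = B), threshold = 0.99)
  expect_equal(rep1@kept, c("A", "B"))
  expect_equal(rep1@removed$removed_id, "A2")
  expect_equal(rep1@removed$kept_id, "A")
  expect_equal(rep1@removed$correlation, 1.0)

  # three identical images: one kept, both removals point at the first
  rep3 <- deduplicate(list(x = A, y = A, z = A))
  expect_equal(rep3@kept, "x")
  expect_equal(rep3@removed$kept_id, c("x", "x"))

  # distinct images all survive (threshold is strict >)
  repd <- deduplicate(list(A = A, B = B), threshold = 0.99)
  expect_equal(repd@kept, c("A", "B"))
  expect_equal(nrow(repd@removed), 0L)

  # idempotence: re-running on the kept set removes nothing
  rep2 <- deduplicate(list(A = A, B = B)[rep1@kept], threshold = 0.99)
  expect_equal(nrow(rep2@removed), 0L)

  expect_equal(length(deduplicate(setNames(list(), character()))@kept), 0L)
})

test_that("deduplicate agrees with an all-pairs Pearson oracle", {
  imgs <- setNames(lapply(1:10, function(i) rand_img(10, 10, seed = 300 + i)),
                   paste0("im", 1:10))
  imgs$im3 <- imgs$im1   # plant one duplicate
  rep1 <- deduplicate(imgs, threshold = 0.99)
  # oracle: greedy scan with stats::cor on flattened grayscale
  kept <- character(); removed <- character()
  for (id in names(imgs)) {
    g <- as.numeric(toGrayscale(imgs[[id]]))
    dup <- FALSE
    for (k in kept)
      if (stats::cor(as.numeric(toGrayscale(imgs[[k]])), g) > 0.99) {
        dup <- TRUE; break
      }
    if (dup) removed <- c(removed, id) else kept <- c(kept, id)
  }
  expect_equal(rep1@kept, kept)
  expect_equal(rep1@removed$removed_id, removed)
})
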