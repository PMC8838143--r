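test_that("manifest loading counts classes and rejects unknown labels", {
  dir <- withr::local_tempdir()
  p <- write_manifest_csv(dir, c("a.png", "b.png", "c.png"),
                          c("MEL", "BEN", "MEL"))
  m <- loadManifest(p)
  cc <- classCounts(m)
  expect_equal(sum(cc["MEL", ]), 2L)
  expect_equal(sum(cc["BEN", ]), 1L)
  expect_true(all(records(m)$split == "unassigned"))

  # header-only CSV
  writeLines("image_path,label", file.path(dir, "empty.csv"))
  expect_equal(nrow(records(loadManifest(file.path(dir, "empty.csv")))), 0L)

  # benign subtypes rejected raw, accepted under mapBenign
  p2 <- write_manifest_csv(dir, c("a.png", "d.png"), c("MEL", "NV"))
  expect_error(loadManifest(p2), "NV")
  m2 <- loadManifest(p2, mapBenign = TRUE)
  expect_equal(records(m2)$label, c("MEL", "BEN"))

  expect_error(loadManifest(file.path(dir, "nope.csv")), "not found")
})

test_that("manifest round-trips through CSV", {
  dir <- withr::local_tempdir()
  m <- LesionManifest(id = c("x", "y", "z"), path = c("x.png", "y.png", "z.png"),
                      label = c("MEL", "BEN", "BEN"),
                      split = c("train", "val", "test"))
  p <- file.path(dir, "out.csv")
  writeManifest(m, p)
  m2 <- loadManifest(p)
  expect_equal(records(m2), records(m))
})

test_that("image reading yields HxWx3 grids on the 0..255 scale", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "black.png")
  writeLesionImage(const_img(4, 4, 0), p)
  a <- readLesionImage(p)
  expect_equal(dim(a), c(4L, 4L, 3L))
  expect_true(all(a == 0))

  # shape contract: 2 rows x 3 cols survives the round trip
  img <- rand_img(2, 3, seed = 9)
  p2 <- file.path(dir, "r.png")
  writeLesionImage(img, p2)
  b <- readLesionImage(p2)
  expect_equal(dim(b), c(2L, 3L, 3L))
  expect_lt(max(abs(b - img)), 0.51)  # 8-bit quantization

  # grayscale sources replicate to three identical channels
  g <- matrix(runif(12), 4, 3)
  pg <- file.path(dir, "g.png")
  EBImage::writeImage(EBImage::Image(t(g)), pg)
  ga <- readLesionImage(pg)
  expect_equal(dim(ga), c(4L, 3L, 3L))
  expect_equal(ga[, , 1], ga[, , 2])
  expect_equal(ga[, , 2], ga[, , 3])

  expect_error(readLesionImage(file.path(dir, "missing.png")), "not found")
})

test_that("stratified split honors the 70/10/20 fractions per class", {
  one_class <- function(n) LesionManifest(id = sprintf("s%03d", seq_len(n)),
                                          label = "MEL")
  s100 <- classCounts(splitDataset(one_class(100), seed = 1))["MEL", ]
  expect_equal(unname(s100[c("train", "val", "test")]), c(70L, 10L, 20L))
  s10 <- classCounts(splitDataset(one_class(10), seed = 1))["MEL", ]
  expect_equal(unname(s10[c("train", "val", "test")]), c(7L, 1L, 2L))

  # two classes: rounding applied independently per class
  m <- LesionManifest(id = sprintf("s%03d", 1:150),
                      label = rep(c("MEL", "BEN"), c(100, 50)))
  cc <- classCounts(splitDataset(m, seed = 3))
  expect_equal(unname(cc["MEL", c("train", "val", "test")]), c(70L, 10L, 20L))
  expect_equal(unname(cc["BEN", c("train", "val", "test")]), c(35L, 5L, 10L))
  expect_equal(unname(cc[, "unassigned"]), c(0L, 0L))
})

test_that("splits partition records and are seed-deterministic", {
  m <- LesionManifest(id = sprintf("s%03d", 1:123),
                      label = rep(c("MEL", "BEN"), c(61, 62)))
  a <- splitDataset(m, seed = 11)
  b <- splitDataset(m, seed = 11)
  c <- splitDataset(m, seed = 12)
  expect_identical(records(a), records(b))
  # different seed: same per-split counts, membership may differ
  expect_equal(classCounts(a), classCounts(c))
  expect_false(identical(records(a)$split, records(c)$split))
  # partition: every record assigned exactly once
  expect_true(all(records(a)$split %in% c("train", "val", "test")))

  expect_error(splitDataset(m, fractions = c(0.5, 0.2, 0.2)), "sum")
  expect_error(splitDataset(a), "unassigned")
})
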