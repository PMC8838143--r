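# Small in-code fixtures shared across tests.

# constant-value H x W x 3 image on the 0..255 scale
const_img <- function(h, w, value = 0) array(value, c(h, w, 3))

# reproducible random image
rand_img <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}

# write a manifest CSV from vectors, returning its path
write_manifest_csv <- function(dir, image_path, label, split = NULL) {
  df <- data.frame(image_path = image_path, label = label,
                   stringsAsFactors = FALSE)
  if (!is.null(split)) df$split <- split
  p <- file.path(dir, "manifest.csv")
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

# a small generated dataset, cached per test run
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateDataset(synthSpec(nPerClass = 8L, seed = 42L))
    cache
  }
})
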