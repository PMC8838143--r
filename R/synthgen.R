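#' @include evaluate.R
NULL

#' Synthetic dataset specification
#'
#' @param nPerClass base images per class.
#' @param imageSize pre-crop edge length in pixels (default 192; the
#'   preprocessing stage crops and resizes to the network input).
#' @param artifactRates named probabilities for \code{hair} arc and
#'   \code{bubble} highlight overlays.
#' @param duplicateRate fraction of the base set appended as exact copies
#'   (for deduplication tests).
#' @param imbalance per-class multipliers (MEL, BEN) applied to
#'   \code{nPerClass}.
#' @param seed generator seed.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(nPerClass = 100L, imageSize = 192L,
                      artifactRates = c(hair = 0.3, bubble = 0.2),
                      duplicateRate = 0, imbalance = c(1, 1), seed = 1L) {
  new("SynthSpec", nPerClass = as.integer(nPerClass),
      imageSize = as.integer(imageSize),
      artifactRates = artifactRates, duplicateRate = duplicateRate,
      imbalance = as.numeric(imbalance), seed = as.integer(seed))
}

#' Render one synthetic lesion image
#'
#' Draws a skin-tone background (random beige base plus per-pixel Gaussian
#' noise) and a centered-but-jittered elliptical lesion. MEL lesions are
#' dark brown with an irregular, radius-perturbed boundary and strong
#' speckle texture; BEN lesions are lighter, smooth and mildly textured.
#' Lesion edges are feathered over ~3 px. Optional artifacts emulate common
#' dermoscopy nuisances: dark hair-line arcs and bright circular gel-bubble
#' highlights. Consumes the current RNG stream; call under a seed for
#' bit-identical output.
#'
#' @param label \code{"MEL"} or \code{"BEN"}.
#' @param spec a \linkS4class{SynthSpec}.
#' @return numeric imageSize x imageSize x 3 array on the 0..255 scale.
#' @export
renderLesion <- function(label = c("MEL", "BEN"), spec = synthSpec()) {
  label <- match.arg(label)
  s <- spec@imageSize
  # skin background: beige base with mild per-channel variation
  base <- c(205, 172, 150) + stats::rnorm(3, 0, 8)
  img <- array(rep(base, each = s * s), c(s, s, 3)) +
    array(stats::rnorm(s * s * 3, 0, 8), c(s, s, 3))

  # lesion geometry: jittered center, class-dependent radius and boundary
  cx <- s / 2 + stats::runif(1, -0.08, 0.08) * s
  cy <- s / 2 + stats::runif(1, -0.08, 0.08) * s
  rad <- stats::runif(1, 0.24, 0.36) * s
  ecc <- stats::runif(1, 0.75, 1.0)
  ang0 <- stats::runif(1, 0, pi)
  row <- matrix(seq_len(s), s, s)
  col <- matrix(seq_len(s), s, s, byrow = TRUE)
  xr <- (col - cx) * cos(ang0) + (row - cy) * sin(ang0)
  yr <- -(col - cx) * sin(ang0) + (row - cy) * cos(ang0)
  theta <- atan2(yr, xr * ecc)
  r <- sqrt((xr * ecc)^2 + yr^2)
  if (label == "MEL") {
    # irregular boundary: low-order random harmonics of the polar angle
    k <- 2:5
    amp <- stats::rnorm(length(k), 0, 0.06)
    phs <- stats::runif(length(k), 0, 2 * pi)
    wob <- rowSums(vapply(seq_along(k),
                          function(i) amp[i] * cos(k[i] * theta + phs[i]),
                          numeric(length(theta))))
    edge <- rad * (1 + matrix(wob, s, s))
    color <- c(82, 52, 46) + stats::rnorm(3, 0, 8)
    texture_sd <- 22
  } else {
    edge <- rad
    color <- c(168, 120, 100) + stats::rnorm(3, 0, 8)
    texture_sd <- 6
  }
  alpha <- 1 / (1 + exp((r - edge) / 1.5))  # feathered mask
  tex <- matrix(stats::rnorm(s * s, 0, texture_sd), s, s)
  for (c3 in 1:3)
    img[, , c3] <- img[, , c3] * (1 - alpha) + (color[c3] + tex) * alpha

  # artifacts
  if (stats::runif(1) < spec@artifactRates[["hair"]])
    img <- draw_hair(img)
  if (stats::runif(1) < spec@artifactRates[["bubble"]])
    img <- draw_bubble(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

# dark arc across the frame, ~1.5 px wide
draw_hair <- function(img) {
  s <- dim(img)[1]
  t <- seq(0, 1, length.out = 4 * s)
  x0 <- stats::runif(2, 1, s); x1 <- stats::runif(2, 1, s)
  bend <- stats::rnorm(2, 0, s / 4)
  px <- (1 - t)^2 * x0[1] + 2 * t * (1 - t) * (x0[1] + bend[1]) + t^2 * x1[1]
  py <- (1 - t)^2 * x0[2] + 2 * t * (1 - t) * (x0[2] + bend[2]) + t^2 * x1[2]
  shade <- stats::runif(1, 30, 70)
  for (i in seq_along(t)) {
    r0 <- round(py[i]); c0 <- round(px[i])
    if (r0 < 0 || r0 > s + 1 || c0 < 0 || c0 > s + 1) next
    rr <- max(1, r0 - 1):min(s, r0 + 1)
    cc <- max(1, c0 - 1):min(s, c0 + 1)
    if (rr[1] > rr[length(rr)] || cc[1] > cc[length(cc)]) next
    img[rr, cc, ] <- shade
  }
  img
}

# bright circular highlight with a soft rim
draw_bubble <- function(img) {
  s <- dim(img)[1]
  cx <- stats::runif(1, 0.2, 0.8) * s
  cy <- stats::runif(1, 0.2, 0.8) * s
  rad <- stats::runif(1, 0.03, 0.07) * s
  row <- matrix(seq_len(s), s, s)
  col <- matrix(seq_len(s), s, s, byrow = TRUE)
  d <- sqrt((col - cx)^2 + (row - cy)^2)
  glow <- pmax(0, 1 - abs(d - rad) / 2) * 0.7 + pmax(0, 1 - d / rad) * 0.25
  for (c3 in 1:3) img[, , c3] <- img[, , c3] + glow * (255 - img[, , c3])
  img
}

#' Generate a full synthetic dataset
#'
#' Renders \code{nPerClass * imbalance} base images per class, appends
#' \code{round(duplicateRate * n_base)} exact copies of randomly chosen base
#' images (ids suffixed \code{"_dup<k>"}), and assembles the matching
#' manifest with all records unassigned. Deterministic for a fixed
#' \code{spec@seed}.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return list with \code{images} (named list of arrays, manifest order)
#'   and \code{manifest} (a \linkS4class{LesionManifest}).
#' @export
generateDataset <- function(spec = synthSpec()) {
  stopifnot(is(spec, "SynthSpec"))
  local_rng(spec@seed)
  counts <- round(spec@nPerClass * spec@imbalance)
  labels <- rep(LABEL_LEVELS, counts)
  ids <- sprintf("%s_%04d", tolower(labels),
                 unlist(lapply(counts, seq_len)))
  images <- vector("list", length(ids))
  names(images) <- ids
  for (i in seq_along(ids)) images[[i]] <- renderLesion(labels[i], spec)

  n_dup <- round(spec@duplicateRate * length(ids))
  if (n_dup > 0L) {
    src <- sample.int(length(ids), n_dup, replace = FALSE)
    dup_ids <- sprintf("%s_dup%d", ids[src], seq_len(n_dup))
    for (j in seq_len(n_dup)) images[[dup_ids[j]]] <- images[[src[j]]]
    labels <- c(labels, labels[src])
    ids <- c(ids, dup_ids)
  }
  list(images = images,
       manifest = LesionManifest(id = ids, path = NA_character_,
                                 label = labels, split = "unassigned"))
}

#' Write a generated dataset to disk
#'
#' Emits one PNG per record plus the manifest CSV, making the generated set
#' usable through the file-based pipeline entry points.
#'
#' @param dataset list from \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return path of the written manifest CSV, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- dataset$manifest@records
  r$path <- file.path(dir, paste0(r$id, ".png"))
  for (i in seq_len(nrow(r)))
    writeLesionImage(dataset$images[[r$id[i]]], r$path[i])
  m <- new("LesionManifest", records = r)
  writeManifest(m, file.path(dir, "manifest.csv"))
}
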