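#' @include dataio.R
NULL

#' Convert an RGB array to grayscale
#'
#' Standard luma combination \code{0.299 R + 0.587 G + 0.114 B} per pixel;
#' the result is real-valued on the source intensity scale.
#'
#' @param pixels numeric H x W x 3 array.
#' @return numeric H x W matrix.
#' @export
toGrayscale <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Intensity histogram of a grayscale image
#'
#' 256-bin count histogram over the 8-bit range; real-valued intensities are
#' binned by truncation to [0, 255].
#'
#' @param gray numeric matrix of intensities on the 0..255 scale.
#' @return integer vector of 256 counts (bins 0..255).
#' @export
grayHistogram <- function(gray) {
  v <- pmin(pmax(floor(as.numeric(gray)), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

#' Correlation index between two grayscale images
#'
#' Pearson-type normalized cross-correlation of the two intensity grids about
#' their scalar means: \deqn{\frac{\sum_{x,y}(I - \bar I)(I' - \bar I')}
#' {\sqrt{\sum_{x,y}(I - \bar I)^2 \sum_{x,y}(I' - \bar I')^2}}.}
#' Images of different sizes are both bilinearly resized to
#' \code{resizeTo} first so the grids align. In \code{mode = "histogram"} the
#' correlation is computed between the 256-bin intensity histograms instead of
#' the pixel grids (no resizing of histograms is needed).
#'
#' A constant image has no variance; its correlation with anything is defined
#' as 0 (with a warning) rather than NaN.
#'
#' @param a,b numeric grayscale matrices on the 0..255 scale.
#' @param mode \code{"image"} (canonical) or \code{"histogram"}.
#' @param resizeTo integer common edge length used when dimensions differ.
#' @return numeric scalar in [-1, 1].
#' @export
imageCorrelation <- function(a, b, mode = c("image", "histogram"),
                             resizeTo = 128L) {
  mode <- match.arg(mode)
  if (mode == "histogram") {
    va <- as.numeric(grayHistogram(a))
    vb <- as.numeric(grayHistogram(b))
  } else {
    if (!identical(dim(a), dim(b))) {
      a <- resize_gray(a, resizeTo)
      b <- resize_gray(b, resizeTo)
    }
    va <- as.numeric(a)
    vb <- as.numeric(b)
  }
  da <- va - mean(va)
  db <- vb - mean(vb)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) {
    warning("constant image: correlation undefined, returning 0")
    return(0)
  }
  sum(da * db) / den
}

resize_gray <- function(gray, target) {
  a <- array(gray, c(dim(gray), 1L))
  cpp_resize_bilinear(a, as.integer(target))[, , 1]
}

#' Remove duplicate images from a record set
#'
#' Greedy scan in manifest order: each image is compared (as grayscale, via
#' \code{\link{imageCorrelation}}) against every previously kept image and
#' discarded when any correlation strictly exceeds \code{threshold}; the first
#' occurrence is always kept.
#'
#' @param images named list of H x W x 3 arrays (names are record ids), in
#'   manifest order.
#' @param threshold correlation threshold in (0, 1]; default 0.99.
#' @param mode correlation mode, see \code{\link{imageCorrelation}}.
#' @return a \linkS4class{DedupReport}.
#' @export
deduplicate <- function(images, threshold = 0.99, mode = c("image", "histogram")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  ids <- names(images)
  if (is.null(ids) && length(images))
    stop("images must be a named list (names are record ids)")
  kept <- character()
  grays <- list()
  removed <- data.frame(removed_id = character(), kept_id = character(),
                        correlation = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(images)) {
    g <- toGrayscale(images[[i]])
    dup_of <- NA_character_; dup_cor <- NA_real_
    for (k in seq_along(kept)) {
      cc <- imageCorrelation(grays[[k]], g, mode = mode)
      if (cc > threshold) { dup_of <- kept[k]; dup_cor <- cc; break }
    }
    if (is.na(dup_of)) {
      kept <- c(kept, ids[i])
      grays[[length(grays) + 1L]] <- g
    } else {
      removed <- rbind(removed,
                       data.frame(removed_id = ids[i], kept_id = dup_of,
                                  correlation = dup_cor,
                                  stringsAsFactors = FALSE))
    }
  }
  new("DedupReport", kept = kept, removed = removed, threshold = threshold)
}

setMethod("show", "DedupReport", function(object) {
  cat(sprintf("DedupReport: kept %d, removed %d (threshold > %g)\n",
              length(object@kept), nrow(object@removed), object@threshold))
  if (nrow(object@removed)) print(head(object@removed, 10))
  invisible(object)
})

#' Write a dedup report CSV
#'
#' @param report a \linkS4class{DedupReport}.
#' @param path output CSV path (columns removed_id, kept_id, correlation).
#' @return \code{path}, invisibly.
#' @export
writeDedupReport <- function(report, path) {
  write.csv(report@removed, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
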