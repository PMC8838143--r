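#' @include dedupe.R
NULL

#' Center-crop an image to a square
#'
#' The crop window of side \code{min(H, W)} is centered; when the excess is
#' odd the extra pixel is dropped from the trailing edge (offset
#' \code{floor((H - S) / 2)}).
#'
#' @param pixels numeric H x W x 3 array.
#' @return numeric S x S x 3 array with S = min(H, W).
#' @export
centerCropSquare <- function(pixels) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[1] >= 1L, d[2] >= 1L)
  s <- min(d[1], d[2])
  r0 <- floor((d[1] - s) / 2)
  c0 <- floor((d[2] - s) / 2)
  pixels[r0 + seq_len(s), c0 + seq_len(s), , drop = FALSE]
}

#' Bilinear resize of a square image
#'
#' Half-pixel-centered (align-corners = false) bilinear interpolation: output
#' pixel centers are mapped to \code{(i + 0.5) * S / target - 0.5} in input
#' index space, with border replication. Bilinear weights are convex, so the
#' output range never exceeds the input range.
#'
#' @param pixels numeric S x S x C array (square: aspect is preserved by the
#'   preceding crop).
#' @param target integer output edge length.
#' @return numeric target x target x C array.
#' @export
resizeBilinear <- function(pixels, target = 128L) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L)
  if (d[1] != d[2]) stop("resizeBilinear expects a square image; crop first")
  target <- as.integer(target)
  if (is.na(target) || target < 1L) stop("target must be a positive integer")
  cpp_resize_bilinear(pixels, target)
}

#' Geometric standardization of one image
#'
#' Center-crop to square then bilinearly resize, yielding the canonical
#' 128 x 128 x 3 network input.
#'
#' @param pixels numeric H x W x 3 array.
#' @param policy a \linkS4class{PreprocessPolicy}.
#' @return numeric target x target x 3 array.
#' @export
preprocessImage <- function(pixels, policy = new("PreprocessPolicy")) {
  stopifnot(is(policy, "PreprocessPolicy"))
  resizeBilinear(centerCropSquare(pixels), policy@targetSize)
}
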