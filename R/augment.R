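#' @include preprocess.R
NULL

#' Balance classes by random oversampling
#'
#' Every class is brought up to the size of the largest class by drawing ids
#' uniformly with replacement. All originals are retained; the appended draws
#' are flagged as duplicates so that online augmentation can be applied to
#' them during training. Intended for the training split only.
#'
#' @param classIds named list mapping label to character vector of record ids
#'   (training split).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{id}, \code{label},
#'   \code{is_duplicate}; equal per-class counts.
#' @export
oversampleBalance <- function(classIds, seed = 1L) {
  stopifnot(is.list(classIds), length(classIds) >= 1L)
  sizes <- vapply(classIds, length, integer(1))
  if (any(sizes == 0L))
    stop("every class needs at least one training sample")
  target <- max(sizes)
  local_rng(seed)
  out <- lapply(names(classIds), function(lab) {
    ids <- classIds[[lab]]
    extra <- target - length(ids)
    dup <- if (extra > 0L) ids[sample.int(length(ids), extra, replace = TRUE)]
           else character()
    data.frame(id = c(ids, dup), label = lab,
               is_duplicate = c(rep(FALSE, length(ids)), rep(TRUE, extra)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Randomly augment one preprocessed image
#'
#' Draws a rotation angle, a horizontal scale jitter and integer per-axis
#' translations from the policy intervals, composes them as a single affine
#' map about the image center (rotation, then scaling, then translation) and
#' resamples bilinearly. Pixels mapped from outside the source are filled
#' with the per-channel median, a skin-tone-like fill. Consumes the current
#' RNG stream, so results are reproducible under \code{set.seed}.
#'
#' @param pixels numeric H x W x C array.
#' @param policy an \linkS4class{AugmentPolicy}.
#' @return augmented array of the same dimensions.
#' @export
randomAugment <- function(pixels, policy = new("AugmentPolicy")) {
  stopifnot(is(policy, "AugmentPolicy"))
  ang <- runif(1, policy@rotationDeg[1], policy@rotationDeg[2])
  sx <- runif(1, min(policy@scaleX, 1), max(policy@scaleX, 1))
  sy <- policy@scaleY
  tr <- sample(seq(policy@translatePx[1], policy@translatePx[2]), 2L,
               replace = TRUE)
  affineTransform(pixels, angle = ang, scaleX = sx, scaleY = sy,
                  translateX = tr[1], translateY = tr[2])
}

#' Affine resampling about the image center
#'
#' Applies rotation by \code{angle} degrees (counter-clockwise positive),
#' anisotropic scaling and translation, in that order, about the image
#' center, with bilinear interpolation. The resampler inverse-maps each
#' output pixel center into the source.
#'
#' @param pixels numeric H x W x C array.
#' @param angle rotation in degrees, counter-clockwise positive.
#' @param scaleX,scaleY scale factors.
#' @param translateX,translateY translation in pixels (x right, y down).
#' @param fill per-channel fill values for exposed pixels; default the
#'   per-channel median of the input.
#' @return transformed array, same dimensions.
#' @export
affineTransform <- function(pixels, angle = 0, scaleX = 1, scaleY = 1,
                            translateX = 0, translateY = 0, fill = NULL) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L)
  if (is.null(fill))
    fill <- apply(pixels, 3L, stats::median)
  th <- angle * pi / 180
  # forward map: p' = T S R p; inverse map applied per output pixel:
  # p = R^-1 S^-1 (p' - t), in (x, y) coordinates with y pointing down
  # (counter-clockwise rotation therefore uses the transposed matrix).
  rot_inv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L,
                    byrow = TRUE)
  sc_inv <- diag(c(1 / scaleX, 1 / scaleY))
  A <- rot_inv %*% sc_inv
  t_in <- -A %*% c(translateX, translateY)
  m <- cbind(A, t_in)
  cpp_affine_bilinear(pixels, m, as.numeric(fill))
}
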