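#' @include AllGenerics.R
NULL

#' Construct a LesionManifest
#'
#' @param id character vector of unique record identifiers.
#' @param path character vector of image file paths (NA for in-memory records).
#' @param label character vector of class labels, \code{"MEL"} or \code{"BEN"}.
#' @param split character vector of split tags; default all
#'   \code{"unassigned"}.
#' @return a \linkS4class{LesionManifest}.
#' @export
LesionManifest <- function(id = character(), path = NA_character_,
                           label = character(), split = "unassigned") {
  n <- length(id)
  records <- data.frame(id = as.character(id),
                        path = rep_len(as.character(path), n),
                        label = rep_len(as.character(label), max(n, 0L))[seq_len(n)],
                        split = rep_len(as.character(split), max(n, 1L))[seq_len(n)],
                        stringsAsFactors = FALSE)
  new("LesionManifest", records = records)
}

#' @rdname records
#' @export
setMethod("records", "LesionManifest", function(x) x@records)

#' @rdname classCounts
#' @export
setMethod("classCounts", "LesionManifest", function(x) {
  r <- x@records
  tab <- table(factor(r$label, LABEL_LEVELS), factor(r$split, SPLIT_LEVELS))
  m <- matrix(as.integer(tab), nrow = length(LABEL_LEVELS),
              dimnames = list(LABEL_LEVELS, SPLIT_LEVELS))
  m
})

setMethod("show", "LesionManifest", function(object) {
  r <- object@records
  cat(sprintf("LesionManifest with %d record(s)\n", nrow(r)))
  if (nrow(r)) {
    cc <- classCounts(object)
    cc <- cbind(cc, total = rowSums(cc))
    print(cc)
  }
  invisible(object)
})

#' Read a manifest CSV
#'
#' The CSV must be comma-separated UTF-8 with a header naming at least
#' \code{image_path} and \code{label}; an optional \code{split} column carries
#' previous split assignments (absent means all records unassigned) and an
#' optional \code{id} column overrides the default ids (the file stem of
#' \code{image_path}).
#'
#' @param path path to the CSV file.
#' @param mapBenign logical; when TRUE the benign subtype labels \code{NV}
#'   (nevus) and \code{SK} (seborrheic keratosis) are folded into \code{BEN}
#'   before validation, keeping the task binary. Raw subtype labels are
#'   otherwise rejected.
#' @return a \linkS4class{LesionManifest}.
#' @export
loadManifest <- function(path, mapBenign = FALSE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("image_path", "label") %in% names(df)))
    stop("manifest must have columns image_path,label[,split]")
  if (mapBenign) df$label[df$label %in% c("NV", "SK", "BEN")] <- "BEN"
  bad <- which(!df$label %in% LABEL_LEVELS)
  if (length(bad))
    stop(sprintf("unknown label %s in manifest row %d",
                 dQuote(df$label[bad[1]]), bad[1]))
  split <- if ("split" %in% names(df)) df$split else "unassigned"
  id <- if ("id" %in% names(df)) df$id else
    sub("\\.[A-Za-z0-9]+$", "", basename(df$image_path))
  LesionManifest(id = id, path = df$image_path, label = df$label,
                 split = split)
}

#' Write a manifest CSV
#'
#' @param manifest a \linkS4class{LesionManifest}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "LesionManifest"))
  r <- manifest@records
  out <- data.frame(id = r$id, image_path = r$path, label = r$label,
                    split = r$split, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an image file as an 8-bit RGB array
#'
#' PNG and JPEG are decoded through \pkg{EBImage}; grayscale sources are
#' replicated to three channels. Values are returned on the 0..255 scale.
#'
#' @param path image file path.
#' @return numeric H x W x 3 array with values in [0, 255].
#' @export
readLesionImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path,
                                           ": ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  # EBImage stores (x, y[, c]) in [0, 1]; transpose to (row=y, col=x)
  if (length(dim(a)) == 2L) {
    a <- array(rep(t(a), 3L), c(rev(dim(a)), 3L))
  } else {
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    a <- aperm(a, c(2L, 1L, 3L))
    if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  }
  a * 255
}

#' Write an 8-bit RGB array as a PNG file
#'
#' @param pixels numeric H x W x 3 array, values in [0, 255].
#' @param path output path ending in \code{.png}.
#' @return \code{path}, invisibly.
#' @export
writeLesionImage <- function(pixels, path) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  a <- aperm(pixels / 255, c(2L, 1L, 3L))
  a[a < 0] <- 0; a[a > 1] <- 1
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/validation/test split
#'
#' Assigns every unassigned record to one of the three splits, independently
#' per class. Within a class of n records the validation and test sets get
#' \code{round(fraction * n)} records (round half up) and the remainder goes
#' to training, so the canonical fractions (0.70, 0.10, 0.20) give exactly
#' 70/10/20 on a class of 100. Membership is drawn by a seeded permutation:
#' the same seed reproduces the same split, different seeds give the same
#' per-split counts with different membership.
#'
#' @param manifest a \linkS4class{LesionManifest} with all records unassigned.
#' @param fractions numeric length-3 (train, val, test) summing to 1.
#' @param seed integer RNG seed.
#' @return a new \linkS4class{LesionManifest} with splits assigned.
#' @export
splitDataset <- function(manifest, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  stopifnot(is(manifest, "LesionManifest"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values summing to 1")
  r <- manifest@records
  if (nrow(r) && any(r$split != "unassigned"))
    stop("all records must be unassigned before splitting")
  rng <- local_rng(seed)
  split <- r$split
  for (lab in unique(r$label)) {
    idx <- which(r$label == lab)
    n <- length(idx)
    n_val <- round_half_up(fractions[2] * n)
    n_test <- round_half_up(fractions[3] * n)
    if (n_val + n_test > n) n_test <- n - n_val
    perm <- idx[sample.int(n)]
    split[perm[seq_len(n_val)]] <- "val"
    split[perm[n_val + seq_len(n_test)]] <- "test"
    split[perm[-seq_len(n_val + n_test)]] <- "train"
  }
  r$split <- split
  new("LesionManifest", records = r)
}

# Seeded RNG scope tied to the caller's frame: the caller's RNG state is
# restored on exit so seeded internals never disturb the user's stream.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
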