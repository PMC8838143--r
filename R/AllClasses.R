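#' @include lcnet-package.R
NULL

LABEL_LEVELS <- c("MEL", "BEN")
SPLIT_LEVELS <- c("train", "val", "test", "unassigned")

#' LesionManifest: ordered image records with labels and split tags
#'
#' Wraps the record table of an image dataset: one row per image with a unique
#' identifier, a file path (may be \code{NA} for in-memory records), a class
#' label (\code{MEL} or \code{BEN}) and a split tag (\code{train}, \code{val},
#' \code{test} or \code{unassigned}).
#'
#' @slot records data.frame with columns \code{id}, \code{path}, \code{label},
#'   \code{split}.
#' @exportClass LesionManifest
setClass("LesionManifest", representation(records = "data.frame"))

setValidity("LesionManifest", function(object) {
  r <- object@records
  need <- c("id", "path", "label", "split")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id)) return("record ids must be unique")
  if (nrow(r) && !all(r$label %in% LABEL_LEVELS))
    return(sprintf("unknown label(s): %s",
                   paste(unique(r$label[!r$label %in% LABEL_LEVELS]), collapse = ", ")))
  if (nrow(r) && !all(r$split %in% SPLIT_LEVELS))
    return("split must be one of train/val/test/unassigned")
  TRUE
})

#' DedupReport: outcome of duplicate elimination
#'
#' @slot kept character vector of retained record ids, in scan order.
#' @slot removed data.frame with columns \code{removed_id}, \code{kept_id},
#'   \code{correlation}.
#' @slot threshold numeric correlation threshold used (strict \code{>}).
#' @exportClass DedupReport
setClass("DedupReport",
         representation(kept = "character", removed = "data.frame",
                        threshold = "numeric"))

setValidity("DedupReport", function(object) {
  if (any(object@removed$removed_id %in% object@kept))
    return("removed and kept ids must be disjoint")
  if (nrow(object@removed) &&
      any(object@removed$correlation <= object@threshold))
    return("every removed pair must exceed the threshold")
  TRUE
})

#' PreprocessPolicy: geometric standardization parameters
#'
#' @slot targetSize integer edge length after resize (pixels, default 128).
#' @slot crop cropping strategy; only \code{"center_square"}.
#' @slot interpolation resampling filter; only \code{"bilinear"}.
#' @exportClass PreprocessPolicy
setClass("PreprocessPolicy",
         representation(targetSize = "integer", crop = "character",
                        interpolation = "character"),
         prototype(targetSize = 128L, crop = "center_square",
                   interpolation = "bilinear"))

setValidity("PreprocessPolicy", function(object) {
  if (object@targetSize < 8L) return("targetSize must be >= 8")
  if (!identical(object@crop, "center_square")) return("unsupported crop")
  if (!identical(object@interpolation, "bilinear"))
    return("unsupported interpolation")
  TRUE
})

#' AugmentPolicy: online affine augmentation ranges
#'
#' Rotation is drawn uniformly from \code{rotationDeg} (degrees,
#' counter-clockwise positive); the horizontal scale factor uniformly from
#' \code{[min(scaleX, 1), max(scaleX, 1)]} with the vertical factor fixed at
#' \code{scaleY}; integer translations independently per axis from
#' \code{translatePx}. The three are composed as one affine map about the
#' image center and resampled bilinearly; pixels mapped from outside the
#' source take the per-channel median (a skin-tone-like fill).
#'
#' @slot rotationDeg numeric length-2 interval, degrees.
#' @slot scaleX numeric anisotropic horizontal scale bound (default 0.8).
#' @slot scaleY numeric vertical scale factor (default 1.0).
#' @slot translatePx numeric length-2 integer interval, pixels.
#' @exportClass AugmentPolicy
setClass("AugmentPolicy",
         representation(rotationDeg = "numeric", scaleX = "numeric",
                        scaleY = "numeric", translatePx = "numeric"),
         prototype(rotationDeg = c(-30, 30), scaleX = 0.8, scaleY = 1.0,
                   translatePx = c(-5, 5)))

setValidity("AugmentPolicy", function(object) {
  if (length(object@rotationDeg) != 2L ||
      abs(sum(object@rotationDeg)) > 1e-9)
    return("rotation interval must be symmetric about 0")
  if (object@scaleX <= 0 || object@scaleY <= 0)
    return("scale factors must be positive")
  if (length(object@translatePx) != 2L ||
      object@translatePx[1] > object@translatePx[2])
    return("translatePx must be an interval")
  TRUE
})

#' SynthSpec: parameters of the synthetic lesion-image generator
#'
#' @slot nPerClass integer base images per class.
#' @slot imageSize integer pre-crop edge length (default 192).
#' @slot artifactRates named numeric, probabilities of \code{hair} and
#'   \code{bubble} overlays per image.
#' @slot duplicateRate numeric fraction of exact duplicates appended.
#' @slot imbalance numeric length-2 per-class multipliers (MEL, BEN).
#' @slot seed integer generator seed.
#' @exportClass SynthSpec
setClass("SynthSpec",
         representation(nPerClass = "integer", imageSize = "integer",
                        artifactRates = "numeric", duplicateRate = "numeric",
                        imbalance = "numeric", seed = "integer"),
         prototype(nPerClass = 100L, imageSize = 192L,
                   artifactRates = c(hair = 0.3, bubble = 0.2),
                   duplicateRate = 0, imbalance = c(1, 1), seed = 1L))

setValidity("SynthSpec", function(object) {
  if (object@nPerClass < 1L) return("nPerClass must be >= 1")
  if (object@imageSize < 32L) return("imageSize must be >= 32")
  p <- c(object@artifactRates, object@duplicateRate)
  if (any(p < 0 | p > 1)) return("rates must be probabilities in [0, 1]")
  if (length(object@imbalance) != 2L || any(object@imbalance <= 0))
    return("imbalance must be two positive multipliers")
  TRUE
})

#' LCNetConfig: structural description of the LCNet architecture
#'
#' Eleven block definitions organised as a stem junction, three 1x1 reduction
#' blocks each followed by 2x2 average pooling, and three groups of two-branch
#' units repeated 2, 4 and 2 times, closed by global average pooling and a
#' fully connected softmax head.
#'
#' @slot inputSize integer spatial input edge (128).
#' @slot inputChannels integer input channels (3).
#' @slot nClasses integer output classes (>= 2).
#' @slot leakySlope numeric LeakyReLU negative-branch slope (0.3).
#' @slot repeats integer length-3 repeat counts of the three unit groups.
#' @slot blocks list of 11 block definitions (id, convs, pool).
#' @exportClass LCNetConfig
setClass("LCNetConfig",
         representation(inputSize = "integer", inputChannels = "integer",
                        nClasses = "integer", leakySlope = "numeric",
                        repeats = "integer", blocks = "list"))

setValidity("LCNetConfig", function(object) {
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (!identical(object@repeats, c(2L, 4L, 2L)))
    return("repeat counts must be (2, 4, 2)")
  if (length(object@blocks) != 11L) return("exactly 11 block definitions")
  if (object@leakySlope <= 0) return("leakySlope must be > 0")
  TRUE
})

#' NetworkStats: structural counts of an architecture
#'
#' @slot nConvLayers integer number of convolutional layers.
#' @slot nKernels integer total kernels (sum of output channels over convs).
#' @slot nLearnableParams numeric total learnable parameters: convolution
#'   weights and biases, two batch-normalization learnables per channel
#'   (running moments excluded), fully connected weights and biases.
#' @exportClass NetworkStats
setClass("NetworkStats",
         representation(nConvLayers = "integer", nKernels = "integer",
                        nLearnableParams = "numeric"))

#' LCNetModel: an instantiated network
#'
#' Holds the computation graph (ordered node list) and all parameter arrays.
#'
#' @slot config the \linkS4class{LCNetConfig} the graph was built from.
#' @slot graph ordered list of graph nodes.
#' @slot params named list of parameter sets keyed by node id.
#' @slot seed integer initialization seed.
#' @exportClass LCNetModel
setClass("LCNetModel",
         representation(config = "LCNetConfig", graph = "list",
                        params = "list", seed = "integer"))

#' TrainConfig: optimization hyperparameters
#'
#' Defaults are the canonical training recipe: SGDM with learning rate 0.001,
#' momentum 0.99, L2 regularization 0.0005, mini-batch 32, at most 100 epochs
#' with early stopping on validation loss.
#'
#' @slot learningRate numeric step size.
#' @slot momentum numeric SGDM momentum in [0, 1).
#' @slot weightDecay numeric L2 coefficient applied inside the gradient.
#' @slot batchSize integer mini-batch size.
#' @slot maxEpochs integer epoch budget.
#' @slot earlyStopPatience integer epochs without validation-loss improvement
#'   before stopping.
#' @slot seed integer seed for shuffling, augmentation and initialization.
#' @slot augment logical; apply online augmentation to training batches.
#' @exportClass TrainConfig
setClass("TrainConfig",
         representation(learningRate = "numeric", momentum = "numeric",
                        weightDecay = "numeric", batchSize = "integer",
                        maxEpochs = "integer", earlyStopPatience = "integer",
                        seed = "integer", augment = "logical"),
         prototype(learningRate = 0.001, momentum = 0.99, weightDecay = 5e-4,
                   batchSize = 32L, maxEpochs = 100L,
                   earlyStopPatience = 10L, seed = 1L, augment = TRUE))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    return("momentum must be in [0, 1)")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
  TRUE
})

#' TrainHistory: per-epoch training record
#'
#' @slot epochs data.frame with columns \code{epoch}, \code{train_loss},
#'   \code{val_loss}, \code{val_accuracy}.
#' @slot stoppedEpoch integer last epoch run.
#' @slot bestEpoch integer epoch whose weights were kept.
#' @exportClass TrainHistory
setClass("TrainHistory",
         representation(epochs = "data.frame", stoppedEpoch = "integer",
                        bestEpoch = "integer"))

setValidity("TrainHistory", function(object) {
  if (object@bestEpoch > object@stoppedEpoch)
    return("bestEpoch cannot exceed stoppedEpoch")
  TRUE
})

#' EvalReport: confusion counts, derived metrics and ROC/AUC
#'
#' MEL is the positive class. Metrics follow the standard confusion-matrix
#' definitions; any zero-denominator metric is reported as 0 with
#' \code{degenerate = TRUE}.
#'
#' @slot counts named integer vector \code{TP, FP, TN, FN}.
#' @slot metrics named numeric \code{ACC, PRE, REC, SPE, F1}.
#' @slot auc numeric area under the ROC curve (NA when scores absent).
#' @slot rocPoints data.frame with columns \code{FPR}, \code{TPR}.
#' @slot degenerate logical; TRUE when any metric had a zero denominator.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(counts = "integer", metrics = "numeric",
                        auc = "numeric", rocPoints = "data.frame",
                        degenerate = "logical"))

setValidity("EvalReport", function(object) {
  if (!identical(names(object@counts), c("TP", "FP", "TN", "FN")))
    return("counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0L)) return("counts must be nonnegative")
  TRUE
})
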